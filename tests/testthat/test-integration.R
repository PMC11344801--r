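test_that("rule_bounds implements the category formulas", {
  e <- expression_profile(c(G1 = 3.0, G2 = 1.5, G3 = 2.5, G4 = 2.0, G5 = 5.0))
  expect_equal(rule_bounds(parse_gpr("G1"), e, reversible = TRUE), c(-3, 3))
  expect_equal(rule_bounds(parse_gpr("G1"), e, reversible = FALSE), c(0, 3))
  expect_equal(rule_bounds(parse_gpr("G2 or G3"), e, reversible = FALSE),
               c(0, 4))
  expect_equal(rule_bounds(parse_gpr("G4 and G5"), e, reversible = TRUE),
               c(-2, 2))
})

test_that("unsupported categories signal a routed condition", {
  e <- expression_profile(c(G1 = 1, G2 = 1, G3 = 1))
  expect_error(rule_bounds(parse_gpr("(G1 and G2) or G3"), e, TRUE),
               class = "gemflux_unsupported_rule")
  expect_error(rule_bounds(parse_gpr(""), e, TRUE),
               class = "gemflux_unsupported_rule")
  expect_error(rule_bounds(parse_gpr("G1 and G9"), e, TRUE), "G9")
})

test_that("essentiality reflects redundancy in the network", {
  fx <- two_chain()
  med <- toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3))
  m <- apply_media(fx$model, med)
  # the only biomass-feeding reaction is essential
  expect_true(reaction_is_essential(m, "BIOMASS"))
  # a parallel chain is redundant
  expect_false(reaction_is_essential(m, "R1_S1"))
  # boundary case: essential_fraction 0 counts only total collapse
  expect_false(reaction_is_essential(m, "R1_S1", essential_fraction = 0))
  expect_true(reaction_is_essential(m, "BIOMASS", essential_fraction = 0))
})

test_that("abundant expression leaves the model unconstrained in effect", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  prof <- make_expression(fx$model, seed = 3, base_level = 50, jitter_sd = 0)
  res <- integrate_expression(m, prof, growth_threshold("s", 1))
  expect_identical(res$report$reopened, character(0))
  expect_equal(res$report$final_growth, 5, tolerance = 1e-9)
})

test_that("a single low-expression bottleneck is reopened to save growth", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  # G1 sits alone on R1_S1; starving it caps growth at 3 + 0.5 < floor 4
  prof <- make_expression(fx$model, seed = 3, low_genes = "G1",
                          base_level = 50, jitter_sd = 0)
  res <- integrate_expression(m, prof, growth_threshold("s", 1 / 4))
  expect_identical(res$report$reopened, "R1_S1")
  expect_identical(unname(res$report$disposition[["R1_S1"]]), "reopened")
  expect_gte(res$report$final_growth, 4 - 1e-9)
  # the reopened reaction's bounds are bit-identical to its prior bounds
  expect_identical(unname(reaction_bounds(res$model, "R1_S1")),
                   unname(reaction_bounds(m, "R1_S1")))
})

test_that("the same constraint is kept when the threshold allows it", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  prof <- make_expression(fx$model, seed = 3, low_genes = "G1",
                          base_level = 50, jitter_sd = 0)
  res <- integrate_expression(m, prof, growth_threshold("s", 1 / 3))
  expect_identical(res$report$reopened, character(0))
  expect_equal(unname(reaction_bounds(res$model, "R1_S1")), c(0, 0.5))
  expect_gte(res$report$final_growth, 3 - 1e-9)
})

test_that("a zero threshold never reopens anything", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  prof <- make_expression(fx$model, seed = 5, low_genes = c("G1", "G6"))
  res <- integrate_expression(m, prof, NULL)
  expect_identical(res$report$reopened, character(0))
})

test_that("every reaction gets exactly one disposition and reports are deterministic", {
  fx <- make_toy_gem(toy_gem_spec(
    n_chains = 3, chain_length = 2, uptake_capacity = c(2, 3, 4),
    rule_categories = c("one-gene", "or", "and", "andor", "none")))
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3, EX_C3 = 4)))
  prof <- make_expression(fx$model, seed = 9, low_genes = "G1")
  r1 <- integrate_expression(m, prof, growth_threshold("s", 1 / 8))
  r2 <- integrate_expression(m, prof, growth_threshold("s", 1 / 8))
  expect_false(any(is.na(r1$report$disposition)))
  expect_identical(r1$report$disposition, r2$report$disposition)
  expect_identical(r1$report$final_bounds, r2$report$final_bounds)
  # andor and unannotated reactions were skipped, not constrained
  cats <- vapply(fx$model$gpr_rules, `[[`, "", "category")
  expect_true(all(r1$report$disposition[cats == "andor"] %in%
                    c("andor_skipped", "essential_locked")))
  expect_true(all(r1$report$disposition[cats == "none"] %in%
                    c("genes_missing", "media_locked", "essential_locked")))
})

test_that("an unreachable threshold warns and falls back to the achievable floor", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  prof <- make_expression(fx$model, seed = 3, base_level = 50, jitter_sd = 0)
  expect_warning(res <- integrate_expression(m, prof, growth_threshold("s", 1 / 10)),
                 "exceeds")
  expect_equal(res$report$effective_floor, 5, tolerance = 1e-9)
  expect_gte(res$report$final_growth, 5 - 1e-9)
})

test_that("doubling time and growth rate are mutual inverses", {
  expect_equal(doubling_time(1), 1)
  expect_equal(doubling_time(0.5), 2)
  expect_equal(growth_rate(doubling_time(0.37)), 0.37, tolerance = 1e-12)
  expect_error(doubling_time(0), "undefined")
  expect_error(growth_rate(-1), "undefined")
})

test_that("missing genes leave reactions at prior bounds", {
  fx <- two_chain()
  m <- apply_media(fx$model, toy_media(fx$model, c(EX_C1 = 2, EX_C2 = 3)))
  vals <- setNames(rep(50, length(fx$model$genes)), fx$model$genes)
  vals <- vals[setdiff(names(vals), "G6")]            # drop R2_S2's only gene
  res <- integrate_expression(m, expression_profile(vals, "s"), NULL)
  expect_identical(unname(res$report$disposition[["R2_S2"]]), "genes_missing")
  expect_identical(unname(reaction_bounds(res$model, "R2_S2")),
                   unname(reaction_bounds(m, "R2_S2")))
})
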