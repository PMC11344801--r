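test_that("generated models hit their analytic optimum", {
  set.seed(5)
  for (i in 1:6) {
    nch <- sample(1:3, 1); len <- sample(1:3, 1)
    fx <- make_toy_gem(toy_gem_spec(
      n_chains = nch, chain_length = len,
      uptake_capacity = round(runif(nch, 0.5, 8), 2),
      internal_capacity = round(runif(nch * len, 0.5, 10), 2),
      rule_categories = c("one-gene", "or", "and", "andor", "none")))
    expect_equal(fba(fx$model)$objective_value, fx$truth$optimum,
                 tolerance = 1e-9)
    expect_equal(fx$truth$optimum, sum(fx$truth$chain_capacity))
    validate_ok <- tryCatch({ gemflux:::validate_model(fx$model); TRUE },
                            error = function(e) FALSE)
    expect_true(validate_ok)
  }
})

test_that("generated models survive the SBML round trip", {
  fx <- make_toy_gem(toy_gem_spec(
    n_chains = 2, chain_length = 2,
    rule_categories = c("one-gene", "or", "and", "andor"),
    planted_essentials = "ESS"))
  p <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(fx$model, p)
  m2 <- read_sbml_model(p)
  expect_equal(fba(m2)$objective_value, fx$truth$optimum, tolerance = 1e-9)
})

test_that("unsatisfiable fixture specs are rejected", {
  expect_error(toy_gem_spec(n_chains = 0), "n_chains")
  expect_error(toy_gem_spec(rule_categories = "xor"), "unknown rule")
  expect_error(toy_gem_spec(bottleneck = list(capacity = 1)), "bottleneck")
  expect_error(make_toy_gem(toy_gem_spec(
    bottleneck = list(reaction_id = "R9_S9", capacity = 1))), "R9_S9")
})

test_that("expression generation is seed-stable and respects planted sets", {
  fx <- two_chain()
  p1 <- make_expression(fx$model, seed = 7, high_genes = "G2",
                        low_genes = "G1")
  p2 <- make_expression(fx$model, seed = 7, high_genes = "G2",
                        low_genes = "G1")
  expect_identical(p1$values, p2$values)
  expect_equal(unname(p1$values["G1"]), 0.5)
  expect_equal(unname(p1$values["G2"]), 8)
  expect_error(make_expression(fx$model, high_genes = "G1", low_genes = "G1"),
               "both high and low")
  p3 <- make_expression(fx$model, seed = 1, jitter_sd = 0)
  expect_true(all(p3$values == 5))
})

test_that("dependency generation plants essentials at 0.9 vs 0.1", {
  fx <- two_chain()
  d0 <- make_dependency(fx$model, seed = 2, essential_genes = "G1",
                        noise_sd = 0)
  expect_true(all(d0$scores[, "G1"] == 0.9))
  expect_true(all(d0$scores[, "G2"] == 0.1))
  expect_error(make_dependency(fx$model, noise_sd = -1), "non-negative")
  d1 <- make_dependency(fx$model, seed = 2, noise_sd = 0.3)
  d2 <- make_dependency(fx$model, seed = 2, noise_sd = 0.3)
  expect_identical(d1$scores, d2$scores)
  expect_true(all(d1$scores >= 0 & d1$scores <= 1))
})

test_that("group-specific essentials are recovered by the delta top-N", {
  fx <- make_toy_gem(toy_gem_spec(n_chains = 3, chain_length = 3,
                                  rule_categories = "one-gene"))
  planted <- c("G1", "G4")
  d <- make_dependency(fx$model, seed = 9, noise_sd = 0.02,
                       group_essentials = list(low = planted,
                                               high = character(0)))
  delta <- dependency_delta(d, "low", "high")
  expect_setequal(as.character(top_dependency_genes(delta, 2)), planted)
})

test_that("the fixture bundle is complete and internally consistent", {
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(dir, toy_gem_spec(n_chains = 2,
                                                  uptake_capacity = c(2, 3)),
                                doubling_time_h = 0.5, seed = 3)
  expect_true(all(file.exists(paths)))
  m <- read_sbml_model(paths[["model"]])
  med <- read_media(paths[["media"]])
  thr <- read_growth_thresholds(paths[["thresholds"]])
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(fba(m)$objective_value, truth$optimum, tolerance = 1e-9)
  mc <- apply_media(m, med)
  expect_equal(fba(mc)$objective_value, truth$optimum, tolerance = 1e-9)
  mat <- read_expression_matrix(paths[["expression"]], model_genes = m$genes)
  expect_setequal(rownames(mat), m$genes)
  expect_identical(colnames(mat), "toy_sample")
  dep <- read_dependency_csv(paths[["dependency"]])
  expect_identical(colnames(dep$scores), m$genes)
})
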