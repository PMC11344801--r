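test_that("the three-part difference criteria follow their formulas", {
  ids <- c("A", "B", "C")
  mk <- function(...) {
    m <- rbind(...)
    rownames(m) <- ids
    m
  }
  low <- group_flux_table("low", mk(c(3.3, 3.3), c(0.40, 0.40), c(0.2, 0.2)))
  high <- group_flux_table("high", mk(c(1.0, 1.0), c(0.39, 0.39), c(-0.2, -0.2)))
  rec <- flag_differential(low, high)
  rownames(rec) <- rec$reaction_id
  # A: rel change |3.3-1|/3.3 ~ 0.70, sample flux 3.3 >= 0.5 -> flagged
  expect_equal(rec["A", "rel_change"], (3.3 - 1) / 3.3, tolerance = 1e-12)
  expect_true(rec["A", "flagged"])
  # B: rel change 2.6% and no sample reaches 0.5 -> not flagged
  expect_false(rec["B", "magnitude_ok"])
  expect_false(rec["B", "flagged"])
  # C: small fluxes but the mean changes sign -> flagged
  expect_true(rec["C", "sign_change"])
  expect_true(rec["C", "flagged"])
})

test_that("label swap flips means but never the flagged set", {
  fx <- two_chain()
  g <- make_flux_groups(fx$model, planted = c(R1_S1 = 0.5, R2_S2 = -0.4),
                        base_flux = 2, noise_sd = 0.05, seed = 4)
  fwd <- flag_differential(g$low, g$high)
  rev <- flag_differential(g$high, g$low)
  expect_identical(fwd$flagged, rev$flagged)
  expect_equal(fwd$mean_low, rev$mean_high, tolerance = 1e-12)
})

test_that("raising either threshold only shrinks the flagged set", {
  fx <- two_chain()
  g <- make_flux_groups(fx$model,
                        planted = c(R1_S1 = 0.5, R1_S2 = 0.15, R2_S1 = 0.08),
                        base_flux = 1, noise_sd = 0.1, seed = 8)
  base <- flag_differential(g$low, g$high)
  for (alt in list(flag_differential(g$low, g$high, rel_threshold = 0.3),
                   flag_differential(g$low, g$high, magnitude = 2))) {
    expect_true(all(alt$flagged <= base$flagged))  # subset
  }
})

test_that("planted effects with zero noise are flagged exactly", {
  fx <- two_chain()
  g <- make_flux_groups(fx$model, planted = c(R1_S1 = 0.5, R2_S2 = -0.3),
                        base_flux = 2, noise_sd = 0, seed = 1)
  rec <- flag_differential(g$low, g$high)
  expect_identical(sort(rec$reaction_id[rec$flagged]),
                   sort(c("R1_S1", "R2_S2")))
})

test_that("identical groups flag nothing", {
  fx <- two_chain()
  g <- make_flux_groups(fx$model, base_flux = 2, noise_sd = 0, seed = 1)
  rec <- flag_differential(g$low, g$high)
  expect_false(any(rec$flagged))
})

test_that("active fraction counts internal reactions above tolerance", {
  fx <- two_chain()   # 5 internal reactions: R1_S1, R1_S2, R2_S1, R2_S2, BIOMASS
  ids <- fx$model$reactions$id
  flux <- setNames(rep(0, length(ids)), ids)
  flux[c("R1_S1", "R1_S2")] <- 1
  tab <- group_flux_table("g", matrix(flux, ncol = 1,
                                      dimnames = list(ids, "s1")))
  expect_equal(active_fraction(tab, fx$model), 2 / 5)
  expect_equal(active_fraction(tab, fx$model, zero_tol = 10), 0)
  zero <- group_flux_table("g", matrix(0, length(ids), 1,
                                       dimnames = list(ids, "s1")))
  expect_equal(active_fraction(zero, fx$model), 0)
})

test_that("subsystem census counts reactions and unique genes", {
  fx <- two_chain()  # Pathway 1: R1_S1 (G1), R1_S2 (G2 or G3)
  rec <- data.frame(reaction_id = c("R1_S1", "R1_S2", "R2_S1", "BIOMASS"),
                    flagged = c(TRUE, TRUE, TRUE, TRUE))
  cen <- subsystem_census(rec, fx$model)
  expect_equal(sum(cen$n_reactions), 4L)
  p1 <- cen[cen$subsystem == "Pathway 1", ]
  expect_identical(p1$n_reactions, 2L)
  expect_identical(p1$n_unique_genes, 3L)
  # unannotated biomass counts in reactions only
  bio <- cen[cen$subsystem == "Biomass", ]
  expect_identical(bio$n_unique_genes, 0L)
  expect_identical(nrow(subsystem_census(rec[0, ], fx$model)), 0L)
})

test_that("mismatched reaction universes are rejected", {
  m1 <- matrix(1, 2, 2, dimnames = list(c("A", "B"), NULL))
  m2 <- matrix(1, 2, 2, dimnames = list(c("A", "C"), NULL))
  expect_error(flag_differential(group_flux_table("l", m1),
                                 group_flux_table("h", m2)),
               "different reaction sets")
})
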