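test_that("dependency deltas are group-mean differences and antisymmetric", {
  scores <- rbind(a1 = c(g1 = 0.9, g2 = 0.5, g3 = 0.1),
                  a2 = c(0.7, 0.5, 0.3),
                  b1 = c(0.2, 0.5, 0.9))
  d <- dependency_dataset(scores, groups = list(low = c("a1", "a2"), high = "b1"))
  delta <- dependency_delta(d, "low", "high")
  expect_equal(unname(delta["g1"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(delta["g2"]), 0)
  expect_equal(dependency_delta(d, "high", "low"), -delta, tolerance = 1e-12)
  expect_error(dependency_delta(d, "low", "nope"), "unknown group")
})

test_that("deltas on a 10-gene toy match a hand-computed vector", {
  set.seed(21)
  genes <- paste0("g", 1:10)
  scores <- matrix(round(runif(40), 3), nrow = 4,
                   dimnames = list(c("a1", "a2", "b1", "b2"), genes))
  d <- dependency_dataset(scores, list(A = c("a1", "a2"), B = c("b1", "b2")))
  manual <- (scores["a1", ] + scores["a2", ]) / 2 -
    (scores["b1", ] + scores["b2", ]) / 2
  delta <- dependency_delta(d, "A", "B")
  attr(delta, "dropped") <- NULL
  expect_equal(delta, manual, tolerance = 1e-12)
})

test_that("NA scores drop the gene and report it", {
  scores <- rbind(a1 = c(g1 = 0.9, g2 = NA), b1 = c(0.1, 0.5))
  d <- dependency_dataset(scores, list(A = "a1", B = "b1"))
  delta <- dependency_delta(d, "A", "B")
  expect_identical(names(delta), "g1")
  expect_identical(attr(delta, "dropped"), "g2")
})

test_that("top-N selection sorts by delta with lexicographic tie-break", {
  delta <- c(z = 0.5, a = 0.5, m = 0.9, k = 0.1, b = 0.5)
  top <- top_dependency_genes(delta, 3)
  expect_identical(as.character(top[1:3]), c("m", "a", "b"))
  expect_true(attr(top, "tied_at_cut"))
  expect_identical(as.character(top_dependency_genes(delta, 5)),
                   c("m", "a", "b", "z", "k"))
  expect_error(top_dependency_genes(delta, 6), "exceeds")
})

test_that("hypergeometric p equals exhaustive enumeration on small universes", {
  # universe of 20, one set of 5; draw lists of 5 and compare tail
  # probabilities with brute-force enumeration over all C(20,5) subsets
  universe <- paste0("u", 1:20)
  set5 <- universe[1:5]
  subsets <- utils::combn(20, 5)
  for (target_overlap in c(4, 2, 0)) {
    gene_list <- c(set5[seq_len(target_overlap)],
                   universe[6:(6 + 4 - target_overlap)])
    res <- ora_hypergeometric(gene_list, list(s = set5), universe)
    overlaps <- colSums(subsets <= 5)
    brute <- mean(overlaps >= target_overlap)
    expect_equal(res$p_value, brute, tolerance = 1e-12,
                 info = paste("overlap", target_overlap))
    expect_identical(res$overlap, as.integer(target_overlap))
    expect_equal(res$enrichment_ratio, target_overlap / (5 * 5 / 20),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the hand-computed five-set example", {
  # p * m / rank = .005 .025 .05 .05 .2 -> step-up keeps monotone sequence
  sets <- lapply(1:5, function(i) paste0("s", i, "_", 1:3))
  names(sets) <- paste0("set", 1:5)
  p_target <- c(0.001, 0.01, 0.03, 0.04, 0.2)
  fake <- data.frame(p_value = p_target)
  expect_equal(stats::p.adjust(p_target, "BH"),
               c(0.005, 0.025, 0.05, 0.05, 0.2), tolerance = 1e-12)
  # and the packaged ORA output is BH over its own p-values, monotone in rank
  universe <- paste0("u", 1:25)
  sets <- list(a = universe[1:5], b = universe[3:10], c = universe[11:14])
  res <- ora_hypergeometric(universe[1:6], sets, universe)
  expect_equal(res$fdr, stats::p.adjust(res$p_value, "BH"), tolerance = 1e-15)
  expect_true(all(diff(res$fdr) >= -1e-12))
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
})

test_that("a single gene set has fdr equal to p", {
  universe <- paste0("u", 1:20)
  res <- ora_hypergeometric(universe[1:5], list(s = universe[1:6]), universe)
  expect_equal(res$fdr, res$p_value)
})

test_that("empty-overlap sets never rank smallest and empty sets are skipped", {
  universe <- paste0("u", 1:20)
  sets <- list(hit = universe[1:5], miss = universe[16:20],
               outside = paste0("x", 1:3))
  res <- ora_hypergeometric(universe[1:5], sets, universe)
  expect_identical(attr(res, "skipped"), "outside")
  expect_identical(res$set_name[1], "hit")
  expect_equal(res$enrichment_ratio[res$set_name == "miss"], 0)
  expect_gte(res$p_value[res$set_name == "miss"], 0.5)
})

test_that("GMT files round-trip", {
  p <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tna\tg9"), p)
  sets <- read_gmt(p)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"), setB = "g9"))
})

test_that("essentiality correlation recovers exact anti-correlation", {
  ko <- data.frame(gene = paste0("g", 1:6),
                   growth_ratio = c(0, 0.2, 0.4, 0.6, 0.8, 0.99))
  dep <- setNames(1 - ko$growth_ratio, ko$gene)
  res <- essentiality_correlation(ko, dep)
  expect_equal(res$pearson_r, -1, tolerance = 1e-12)
  expect_identical(res$n, 6L)
})

test_that("correlation matches the closed-form Pearson and t-test p", {
  set.seed(33)
  ko <- data.frame(gene = paste0("g", 1:20),
                   growth_ratio = runif(20, 0, 0.99))
  dep <- setNames(runif(20), ko$gene)
  res <- essentiality_correlation(ko, dep)
  r_manual <- sum((ko$growth_ratio - mean(ko$growth_ratio)) *
                    (dep - mean(dep))) /
    sqrt(sum((ko$growth_ratio - mean(ko$growth_ratio))^2) *
           sum((dep - mean(dep))^2))
  expect_equal(res$pearson_r, r_manual, tolerance = 1e-12)
  ct <- stats::cor.test(ko$growth_ratio, dep)
  expect_equal(res$p_value, ct$p.value, tolerance = 1e-9)
})

test_that("degenerate correlation inputs raise informative errors", {
  ko <- data.frame(gene = c("g1", "g2", "g3"),
                   growth_ratio = c(0.1, 0.2, 0.3))
  expect_error(essentiality_correlation(ko, c(g1 = 0.5)), "fewer than 3")
  expect_error(essentiality_correlation(ko, setNames(rep(0.5, 3), ko$gene)),
               "zero variance")
  # max_ratio filter: ratio-1 genes are predicted non-essential and excluded
  ko2 <- rbind(ko, data.frame(gene = "g4", growth_ratio = 1.0))
  dep <- setNames(c(0.9, 0.8, 0.7, 0.1), ko2$gene)
  expect_identical(essentiality_correlation(ko2, dep)$n, 3L)
})
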