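#' Gene-dependency dataset
#'
#' CRISPR knockout screens summarise how essential each gene is for a cell
#' line's growth as a dependency score in `[0, 1]` (0.75 means knockdown cuts
#' growth by 75%). Cell lines are partitioned into labelled groups (e.g.
#' tumour subtypes) for the delta analysis.
#'
#' @param scores Numeric matrix, cell lines x genes, values in `[0, 1]`.
#' @param groups Named list, group label -> character vector of line ids.
#' @return An object of class `dependency_dataset`.
#' @export
dependency_dataset <- function(scores, groups = list()) {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            !is.null(colnames(scores)))
  rng <- range(scores, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("dependency scores must lie in [0, 1]")
  for (g in names(groups)) {
    missing <- setdiff(groups[[g]], rownames(scores))
    if (length(missing))
      stop("group '", g, "' references unknown cell line(s): ",
           paste(missing, collapse = ", "))
  }
  structure(list(scores = scores, groups = groups),
            class = "dependency_dataset")
}

#' Read a DepMap-style dependency CSV
#'
#' Cell lines as rows (first column), genes as columns; `"SYMBOL (entrez)"`
#' headers are reduced to the symbol.
#'
#' @param path CSV path.
#' @param groups Passed to [dependency_dataset()].
#' @return A `dependency_dataset`.
#' @export
read_dependency_csv <- function(path, groups = list()) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  colnames(m) <- strip_entrez(colnames(m))
  dependency_dataset(m, groups)
}

#' @export
print.dependency_dataset <- function(x, ...) {
  cat("<dependency_dataset> ", nrow(x$scores), " cell line(s) x ",
      ncol(x$scores), " gene(s)", sep = "")
  if (length(x$groups))
    cat("; groups: ", paste(sprintf("%s (n=%d)", names(x$groups),
                                    lengths(x$groups)), collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

#' Per-gene difference of group-mean dependency
#'
#' For each gene, `mean(score in group_a) - mean(score in group_b)`. Genes
#' with a missing score in any member line of either group are dropped and
#' listed in the `dropped` attribute.
#'
#' @param data A `dependency_dataset`.
#' @param group_a,group_b Group labels (the convention "a minus b" means a
#'   positive delta marks genes the `group_a` lines depend on more).
#' @return Named numeric vector of deltas, attribute `dropped`.
#' @export
dependency_delta <- function(data, group_a, group_b) {
  for (g in c(group_a, group_b)) {
    if (!g %in% names(data$groups)) stop("unknown group: ", g)
    if (!length(data$groups[[g]])) stop("group '", g, "' is empty")
  }
  a <- data$scores[data$groups[[group_a]], , drop = FALSE]
  b <- data$scores[data$groups[[group_b]], , drop = FALSE]
  ok <- !apply(is.na(a), 2, any) & !apply(is.na(b), 2, any)
  delta <- colMeans(a)[ok] - colMeans(b)[ok]
  attr(delta, "dropped") <- colnames(data$scores)[!ok]
  delta
}

#' Top-N genes by dependency delta
#'
#' @param delta Named numeric vector (see [dependency_delta()]).
#' @param n Number of genes to return.
#' @return Character vector of gene ids, sorted by decreasing delta with
#'   lexicographic tie-break; attribute `tied_at_cut` flags whether the
#'   cutoff fell inside a tie group.
#' @export
top_dependency_genes <- function(delta, n = 250) {
  if (n > length(delta))
    stop("n (", n, ") exceeds the number of genes (", length(delta), ")")
  ord <- order(-delta, names(delta))
  sel <- names(delta)[ord[seq_len(n)]]
  tied <- n < length(delta) && delta[[ord[n]]] == delta[[ord[n + 1]]]
  attr(sel, "tied_at_cut") <- tied
  sel
}

#' Read a GMT gene-set collection
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the overlap with `gene_list` is larger
#' than expected by chance given a reference universe, using the
#' hypergeometric upper tail `P(X >= overlap)`. P-values are adjusted across
#' sets by Benjamini-Hochberg; the enrichment ratio is the observed overlap
#' over the expected overlap `list_size * set_size / reference_size`.
#'
#' @param gene_list Character vector of query genes (e.g. the top-N
#'   dependency genes).
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param reference Character vector defining the universe; set sizes, list
#'   size and overlaps are all computed within it.
#' @return Data frame of class `ora_result` with columns `set_name`,
#'   `set_size`, `list_size`, `overlap`, `enrichment_ratio`, `p_value`,
#'   `fdr`, sorted by p-value. Sets with no genes in the reference are
#'   skipped (recorded in the `skipped` attribute).
#' @export
ora_hypergeometric <- function(gene_list, gene_sets, reference) {
  if (!length(gene_list)) stop("gene_list is empty")
  reference <- unique(reference)
  gene_list <- unique(intersect(gene_list, reference))
  if (!length(gene_list))
    stop("no query gene is present in the reference universe")
  N <- length(reference)
  k <- length(gene_list)
  sets <- lapply(gene_sets, function(s) unique(intersect(s, reference)))
  skipped <- names(sets)[lengths(sets) == 0]
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("no gene set overlaps the reference universe")
  rows <- lapply(names(sets), function(nm) {
    m <- length(sets[[nm]])
    x <- length(intersect(gene_list, sets[[nm]]))
    p <- stats::phyper(x - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set_name = nm, set_size = m, list_size = k, overlap = x,
               enrichment_ratio = x / (k * m / N), p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("ora_result", "data.frame")
  out
}

#' Correlate knockout growth ratios with dependency scores
#'
#' Pearson correlation between in-silico single-gene knockout growth ratios
#' and experimental dependency scores, restricted to genes predicted to
#' affect growth (`growth_ratio < max_ratio`). A negative correlation is the
#' expected direction: the more a knockout hurts simulated growth (low
#' ratio), the higher the experimental dependency should be. The p-value
#' uses the t transform of r with n - 2 degrees of freedom.
#'
#' @param ko A `ko_screen` (or data frame with `gene`, `growth_ratio`).
#' @param dependency Named numeric vector, gene -> dependency score.
#' @param max_ratio Keep genes with `growth_ratio < max_ratio` (default 1.0).
#' @return List with `pearson_r`, `p_value`, `n`.
#' @export
essentiality_correlation <- function(ko, dependency, max_ratio = 1.0) {
  keep <- ko$growth_ratio < max_ratio
  genes <- intersect(ko$gene[keep], names(dependency))
  n <- length(genes)
  if (n < 3)
    stop("fewer than 3 genes remain after filtering (n = ", n, ")")
  x <- ko$growth_ratio[match(genes, ko$gene)]
  y <- dependency[genes]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in ",
         if (stats::sd(x) == 0) "growth ratios" else "dependency scores")
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(pearson_r = r, p_value = p, n = n)
}
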