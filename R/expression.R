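#' Per-sample expression profile
#'
#' Holds the normalised expression values (log2(TPM+1) scale by default) used
#' as flux bounds during integration. Values must be finite and non-negative.
#'
#' @param values Named numeric vector, gene id -> expression.
#' @param sample_id Sample label.
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(values, sample_id = "sample") {
  values <- unlist(values)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("expression values must be named by gene id")
  if (any(!is.finite(values)) || any(values < 0))
    stop("expression values must be finite and non-negative")
  structure(list(values = values, sample_id = sample_id),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("<expression_profile> ", x$sample_id, ": ", length(x$values),
      " gene(s), range [", format(min(x$values), digits = 4), ", ",
      format(max(x$values), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Read a genes-by-samples expression table
#'
#' Reads a TSV/CSV matrix with genes either as rows (first column holds gene
#' ids) or as columns (CCLE layout: first column holds sample ids, remaining
#' header fields are genes). Orientation is auto-detected by matching header
#' fields against `model_genes` when provided, otherwise genes are assumed to
#' be rows. DepMap-style `"SYMBOL (entrez)"` column headers are reduced to the
#' symbol.
#'
#' @param path File path; delimiter inferred from the extension.
#' @param model_genes Optional character vector used for orientation
#'   detection.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_matrix <- function(path, model_genes = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"")
  header_genes <- strip_entrez(names(df)[-1])
  genes_in_cols <- !is.null(model_genes) &&
    mean(header_genes %in% model_genes) >
      mean(strip_entrez(df[[1]]) %in% model_genes)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (genes_in_cols) {
    rownames(m) <- df[[1]]
    m <- t(m)
    rownames(m) <- strip_entrez(rownames(m))
  } else {
    rownames(m) <- strip_entrez(df[[1]])
    colnames(m) <- names(df)[-1]
  }
  m
}

strip_entrez <- function(x) sub("^(.*\\S)\\s+\\(\\d+\\)$", "\\1", x)

#' Extract one sample's profile from an expression matrix
#'
#' @param mat Genes x samples matrix (see [read_expression_matrix()]).
#' @param sample_id Column to extract.
#' @return An `expression_profile`.
#' @export
profile_from_matrix <- function(mat, sample_id) {
  if (!sample_id %in% colnames(mat))
    stop("sample '", sample_id, "' not in expression matrix")
  expression_profile(setNames(mat[, sample_id], rownames(mat)), sample_id)
}

#' Experimental growth threshold for one sample
#'
#' Converts an experimentally measured doubling time into the minimum
#' admissible model-predicted growth rate. Because biomass flux is in
#' g/gDW/h, growth rate and doubling time are mutual inverses:
#' `growth_min = 1 / doubling_time_h`.
#'
#' @param sample_id Sample label.
#' @param doubling_time_h Doubling time in hours (> 0).
#' @return An object of class `growth_threshold` with fields `sample_id`,
#'   `doubling_time_h`, `growth_min`.
#' @export
growth_threshold <- function(sample_id, doubling_time_h) {
  if (!is.finite(doubling_time_h) || doubling_time_h <= 0)
    stop("doubling_time_h must be a positive number")
  structure(list(sample_id = sample_id,
                 doubling_time_h = doubling_time_h,
                 growth_min = 1 / doubling_time_h),
            class = "growth_threshold")
}

#' Read per-sample doubling times
#'
#' YAML/JSON layout: `{sample_id: doubling_time_h, ...}` or
#' `{thresholds: {...}}`.
#'
#' @param path File path.
#' @return Named list of `growth_threshold` objects.
#' @export
read_growth_thresholds <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$thresholds)) raw <- raw$thresholds
  out <- lapply(names(raw), function(s) growth_threshold(s, as.numeric(raw[[s]])))
  setNames(out, names(raw))
}

#' Convert a growth rate to a doubling time
#'
#' Biomass flux is expressed in g/gDW/h, so predicted growth rate and
#' doubling time are mutual inverses: a growth rate of 0.22 g/gDW/h is a
#' doubling time of about 4.5 h.
#'
#' @param growth Growth rate (g/gDW/h), > 0.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(growth) {
  if (any(!is.finite(growth) | growth <= 0))
    stop("doubling time is undefined for growth <= 0")
  1 / growth
}

#' @rdname doubling_time
#' @param doubling_time_h Doubling time in hours, > 0.
#' @return `growth_rate()`: growth rate in g/gDW/h.
#' @export
growth_rate <- function(doubling_time_h) {
  if (any(!is.finite(doubling_time_h) | doubling_time_h <= 0))
    stop("growth rate is undefined for doubling time <= 0")
  1 / doubling_time_h
}
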