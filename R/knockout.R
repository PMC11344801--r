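#' Single-gene knockout
#'
#' Sets the gene to absent, evaluates every reaction's GPR boolean rule, and
#' closes (bounds 0,0) each reaction whose rule evaluates false. The growth
#' ratio is the knockout FBA optimum over the baseline optimum; a baseline of
#' 0 gives a ratio of 1 when the knockout optimum is also 0.
#'
#' @param model A `metabolic_model`.
#' @param gene A gene id present in the model.
#' @param baseline Optional precomputed baseline optimum.
#' @return An object of class `knockout_result`: list with `gene`,
#'   `growth_ratio`, `disabled_reactions`.
#' @examples
#' fx <- make_toy_gem(toy_gem_spec(n_chains = 2, rule_categories = "or"))
#' gene_knockout(fx$model, fx$model$genes[1])$growth_ratio
#' @export
gene_knockout <- function(model, gene, baseline = NULL) {
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  if (is.null(baseline)) baseline <- fba(model)$objective_value
  if (is.na(baseline)) baseline <- 0
  states <- setNames(FALSE, gene)
  disabled <- model$reactions$id[!vapply(model$gpr_rules, eval_gpr,
                                         logical(1), gene_states = states)]
  ko_model <- model
  for (rid in disabled) ko_model <- set_reaction_bounds(ko_model, rid, 0, 0)
  ko_opt <- if (length(disabled)) fba(ko_model)$objective_value else baseline
  if (is.na(ko_opt)) ko_opt <- 0
  ratio <- if (baseline > 0) ko_opt / baseline else 1
  structure(list(gene = gene, growth_ratio = ratio,
                 disabled_reactions = disabled),
            class = "knockout_result")
}

#' @export
print.knockout_result <- function(x, ...) {
  cat("<knockout_result>", x$gene, "ratio", format(x$growth_ratio, digits = 6),
      "| disabled:", length(x$disabled_reactions), "reaction(s)\n")
  invisible(x)
}

#' Screen all genes by single knockout
#'
#' Each gene is deleted independently against the same baseline optimum.
#'
#' @param model A solvable `metabolic_model`.
#' @param genes Subset of gene ids; default all model genes, in the model's
#'   gene order.
#' @return An object of class `ko_screen`: data frame with columns `gene`,
#'   `growth_ratio`, `n_disabled_reactions`, carrying the full
#'   `knockout_result` list as an attribute.
#' @export
knockout_screen <- function(model, genes = NULL) {
  if (is.null(genes)) genes <- model$genes
  unknown <- setdiff(genes, model$genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  baseline <- fba(model)$objective_value
  results <- lapply(genes, gene_knockout, model = model, baseline = baseline)
  out <- data.frame(
    gene = genes,
    growth_ratio = vapply(results, `[[`, numeric(1), "growth_ratio"),
    n_disabled_reactions = vapply(results, function(r)
      length(r$disabled_reactions), integer(1)),
    stringsAsFactors = FALSE)
  attr(out, "results") <- results
  attr(out, "baseline") <- baseline
  class(out) <- c("ko_screen", "data.frame")
  out
}

#' Write a knockout screen as TSV
#'
#' @param screen A `ko_screen`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ko_screen <- function(screen, path) {
  utils::write.table(as.data.frame(screen), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
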