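#' Flux table for one sample group
#'
#' Collects the flux vectors of a group's member samples and precomputes the
#' per-reaction mean and standard error used by the differential criteria.
#'
#' @param label Group label (e.g. `"low-grade"`).
#' @param fluxes Numeric matrix, reactions x samples (rownames are reaction
#'   ids), or a list of `flux_solution` objects.
#' @return An object of class `group_flux_table`.
#' @export
group_flux_table <- function(label, fluxes) {
  if (is.list(fluxes) && !is.matrix(fluxes)) {
    vecs <- lapply(fluxes, function(s)
      if (inherits(s, "flux_solution")) s$fluxes else unlist(s))
    fluxes <- do.call(cbind, vecs)
  }
  stopifnot(is.matrix(fluxes), !is.null(rownames(fluxes)))
  se <- apply(fluxes, 1, function(v)
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0)
  structure(list(label = label, fluxes = fluxes,
                 mean = rowMeans(fluxes), se = se),
            class = "group_flux_table")
}

#' @export
print.group_flux_table <- function(x, ...) {
  cat("<group_flux_table> ", x$label, ": ", nrow(x$fluxes), " reactions x ",
      ncol(x$fluxes), " sample(s)\n", sep = "")
  invisible(x)
}

#' Fraction of internal reactions carrying flux
#'
#' The proportion of non-exchange reactions with |flux| above `zero_tol` in
#' at least one sample of any supplied group.
#'
#' @param tables List of `group_flux_table`s (or a single one).
#' @param model The `metabolic_model` the fluxes come from (identifies
#'   exchange reactions).
#' @param zero_tol Zero tolerance, mmol/gDW/h.
#' @return Proportion in `[0, 1]`.
#' @export
active_fraction <- function(tables, model, zero_tol = 1e-6) {
  if (inherits(tables, "group_flux_table")) tables <- list(tables)
  internal <- model$reactions$id[!exchange_reactions(model)]
  if (!length(internal)) return(0)
  active <- rep(FALSE, length(internal))
  for (tab in tables) {
    sub <- tab$fluxes[internal, , drop = FALSE]
    active <- active | apply(abs(sub) > zero_tol, 1, any)
  }
  mean(active)
}

#' Flag differential reactions between two groups
#'
#' A reaction is flagged when (a) the relative change between the group mean
#' fluxes is at least `rel_threshold` and some sample in either group carries
#' |flux| >= `magnitude`, or (b) the mean flux changes direction between the
#' groups. The relative change is `|mean_a - mean_b| / max(|mean_a|,
#' |mean_b|)` (0 when both means are 0); all intermediate quantities are
#' returned so alternative combinations of the criteria can be audited.
#'
#' @param low,high `group_flux_table`s over the same reaction set.
#' @param rel_threshold Minimum relative change (default 0.10).
#' @param magnitude Minimum absolute sample flux (default 0.5 mmol/gDW/h).
#' @param model Optional `metabolic_model` supplying subsystem tags.
#' @param zero_tol Zero tolerance for the sign-change test.
#' @return Data frame of class `differential_flux` with columns `reaction_id`,
#'   `mean_low`, `mean_high`, `se_low`, `se_high`, `rel_change`,
#'   `magnitude_ok`, `sign_change`, `flagged`, `subsystem`.
#' @export
flag_differential <- function(low, high, rel_threshold = 0.10, magnitude = 0.5,
                              model = NULL, zero_tol = 1e-6) {
  stopifnot(inherits(low, "group_flux_table"), inherits(high, "group_flux_table"))
  if (!setequal(rownames(low$fluxes), rownames(high$fluxes)))
    stop("the two groups cover different reaction sets")
  ids <- rownames(low$fluxes)
  mh <- high$mean[ids]; ml <- low$mean[ids]
  denom <- pmax(abs(ml), abs(mh))
  rel <- ifelse(denom > 0, abs(ml - mh) / denom, 0)
  max_abs <- pmax(apply(abs(low$fluxes[ids, , drop = FALSE]), 1, max),
                  apply(abs(high$fluxes[ids, , drop = FALSE]), 1, max))
  magnitude_ok <- max_abs >= magnitude
  sign_change <- (ml > zero_tol & mh < -zero_tol) |
    (ml < -zero_tol & mh > zero_tol)
  flagged <- (rel >= rel_threshold & magnitude_ok) | sign_change
  subsystem <- if (!is.null(model))
    model$reactions$subsystem[match(ids, model$reactions$id)]
  else rep(NA_character_, length(ids))
  out <- data.frame(reaction_id = ids, mean_low = unname(ml),
                    mean_high = unname(mh),
                    se_low = unname(low$se[ids]), se_high = unname(high$se[ids]),
                    rel_change = unname(rel), magnitude_ok = unname(magnitude_ok),
                    sign_change = unname(sign_change), flagged = unname(flagged),
                    subsystem = subsystem, stringsAsFactors = FALSE)
  class(out) <- c("differential_flux", "data.frame")
  out
}

#' Tabulate flagged reactions by subsystem
#'
#' Counts flagged reactions and the unique genes in their GPR rules per
#' subsystem (reactions without a gene association contribute to the
#' reaction count only).
#'
#' @param records A `differential_flux` data frame (only flagged rows are
#'   counted).
#' @param model The `metabolic_model` carrying subsystem tags and GPRs.
#' @return Data frame with columns `subsystem`, `n_reactions`,
#'   `n_unique_genes`, sorted by decreasing reaction count.
#' @export
subsystem_census <- function(records, model) {
  flagged <- records[records$flagged, , drop = FALSE]
  if (!nrow(flagged))
    return(data.frame(subsystem = character(0), n_reactions = integer(0),
                      n_unique_genes = integer(0)))
  idx <- match(flagged$reaction_id, model$reactions$id)
  subsys <- model$reactions$subsystem[idx]
  subsys[is.na(subsys) | !nzchar(subsys)] <- "(unassigned)"
  rows <- lapply(split(idx, subsys), function(ii) {
    genes <- unique(unlist(lapply(model$gpr_rules[ii], `[[`, "genes")))
    data.frame(n_reactions = length(ii),
               n_unique_genes = length(genes))
  })
  out <- do.call(rbind, rows)
  out <- data.frame(subsystem = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$n_reactions, out$subsystem), , drop = FALSE]
}
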