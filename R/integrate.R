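#' Expression-derived bounds for one reaction
#'
#' Maps expression values onto flux bounds according to the GPR rule
#' category:
#' \describe{
#'   \item{one-gene}{lower = -E (or 0 if irreversible), upper = +E.}
#'   \item{or (isoenzymes)}{the expression of the alternative enzymes is
#'     summed: lower = -sum(E_i) or 0, upper = sum(E_i). Any isoenzyme can
#'     carry the reaction, so capacity is taken as cumulative.}
#'   \item{and (subunits)}{the minimum subunit expression is limiting:
#'     lower = -min(E_i) or 0, upper = min(E_i).}
#' }
#' Mixed `andor` rules and empty rules are not integrable and raise a
#' condition of class `gemflux_unsupported_rule`, which the integration loop
#' catches and routes to a skip disposition.
#'
#' @param rule A `gpr_rule` with category `one-gene`, `or` or `and`.
#' @param expression An `expression_profile` containing every rule gene.
#' @param reversible Is the reaction reversible? Irreversible reactions keep
#'   a lower bound of 0.
#' @return Numeric `c(lower, upper)`.
#' @examples
#' e <- expression_profile(c(G1 = 1.5, G2 = 2.5))
#' rule_bounds(parse_gpr("G1 or G2"), e, reversible = FALSE)
#' @export
rule_bounds <- function(rule, expression, reversible) {
  stopifnot(inherits(rule, "gpr_rule"), inherits(expression, "expression_profile"))
  if (!rule$category %in% c("one-gene", "or", "and")) {
    stop(structure(class = c("gemflux_unsupported_rule", "error", "condition"),
                   list(message = paste0("rule category '", rule$category,
                                         "' is not integrable"),
                        call = sys.call())))
  }
  missing <- setdiff(rule$genes, names(expression$values))
  if (length(missing))
    stop("expression profile lacks gene(s): ", paste(missing, collapse = ", "))
  e <- expression$values[rule$genes]
  up <- switch(rule$category,
               "one-gene" = unname(e),
               "or" = sum(e),
               "and" = min(e))
  c(if (reversible) -up else 0, up)
}

#' Is a reaction essential for growth?
#'
#' A reaction is essential when closing it (bounds 0,0) drops the FBA
#' optimum below `essential_fraction` times the unperturbed optimum. The
#' model is left unchanged.
#'
#' @param model A solvable `metabolic_model`.
#' @param reaction_id Reaction to test.
#' @param essential_fraction Fraction of baseline growth below which the
#'   reaction counts as essential (default 0.01).
#' @param baseline Optional precomputed baseline optimum (saves one solve).
#' @return Logical scalar.
#' @export
reaction_is_essential <- function(model, reaction_id, essential_fraction = 0.01,
                                  baseline = NULL) {
  if (is.null(baseline)) baseline <- fba(model)$objective_value
  if (is.na(baseline))
    stop("baseline model is infeasible; check media constraints before ",
         "testing essentiality")
  ko <- set_reaction_bounds(model, reaction_id, 0, 0)
  val <- fba(ko)$objective_value
  if (is.na(val)) val <- 0
  # at fraction 0 only a total growth collapse counts as essential
  val < max(essential_fraction * baseline - 1e-12, 1e-9)
}

#' Integrate an expression profile under a growth threshold
#'
#' The sequential constrain/check/relax loop. Reactions are visited in
#' canonical order; for each one the loop decides a disposition:
#' \describe{
#'   \item{media_locked}{exchange bound fixed by the medium; left alone.}
#'   \item{essential_locked}{closing the reaction collapses growth of the
#'     current model; left at its prior bounds.}
#'   \item{andor_skipped}{mixed and/or rule, not integrable.}
#'   \item{genes_missing}{no gene association, or a required gene is absent
#'     from the profile; left at prior bounds.}
#'   \item{constrained}{expression-derived bounds applied and kept.}
#'   \item{reopened}{expression-derived bounds were tried but forced the FBA
#'     optimum below the growth threshold; prior bounds restored.}
#' }
#' Whenever the media-constrained model already met the threshold, the final
#' model's optimum is at least `threshold$growth_min`; if the threshold was
#' unattainable to begin with, a warning is recorded and the achievable
#' optimum acts as the effective floor.
#'
#' @param model A media-constrained `metabolic_model`.
#' @param expression An `expression_profile`.
#' @param threshold A `growth_threshold` (or `NULL` for a floor of 0).
#' @param essential_fraction Passed to [reaction_is_essential()].
#' @param order `"document"` (canonical, default) or `"id"` (sorted).
#' @param objective_tol Absolute tolerance when comparing the FBA optimum to
#'   the floor.
#' @return A list with `model` (constrained) and `report`
#'   (`integration_report`).
#' @export
integrate_expression <- function(model, expression, threshold,
                                 essential_fraction = 0.01,
                                 order = c("document", "id"),
                                 objective_tol = 1e-9) {
  order <- match.arg(order)
  stopifnot(inherits(expression, "expression_profile"))
  growth_min <- if (is.null(threshold)) 0 else threshold$growth_min
  n_solves <- 0L
  solve_opt <- function(m) {
    n_solves <<- n_solves + 1L
    v <- fba(m)$objective_value
    if (is.na(v)) 0 else v
  }
  baseline <- solve_opt(model)
  warn <- character(0)
  floor_eff <- growth_min
  if (baseline < growth_min - objective_tol) {
    warn <- sprintf(paste0("growth threshold %.6g exceeds the media-",
                           "constrained optimum %.6g; using the achievable ",
                           "optimum as the effective floor"),
                    growth_min, baseline)
    warning(warn)
    floor_eff <- baseline
  }
  ids <- model$reactions$id
  idx_order <- if (order == "id") order(ids) else seq_along(ids)
  disposition <- setNames(rep(NA_character_, length(ids)), ids)
  reopened <- character(0)
  current_opt <- baseline
  for (i in idx_order) {
    rid <- ids[i]
    if (rid %in% model$media_locked) {
      disposition[rid] <- "media_locked"; next
    }
    n_solves <- n_solves + 1L  # the closed-reaction solve inside the check
    if (reaction_is_essential(model, rid, essential_fraction,
                              baseline = current_opt)) {
      disposition[rid] <- "essential_locked"; next
    }
    rule <- model$gpr_rules[[i]]
    if (rule$category == "andor") {
      disposition[rid] <- "andor_skipped"; next
    }
    if (rule$category == "none" ||
        !all(rule$genes %in% names(expression$values))) {
      disposition[rid] <- "genes_missing"; next
    }
    prior <- reaction_bounds(model, rid)
    b <- rule_bounds(rule, expression, reversible = prior[["lower"]] < 0)
    trial <- set_reaction_bounds(model, rid, b[1], b[2])
    val <- solve_opt(trial)
    if (val < floor_eff - objective_tol) {
      disposition[rid] <- "reopened"
      reopened <- c(reopened, rid)
    } else {
      model <- trial
      current_opt <- val
      disposition[rid] <- "constrained"
    }
  }
  final_growth <- solve_opt(model)
  report <- structure(list(
    sample_id = expression$sample_id,
    disposition = disposition,
    reopened = reopened,
    final_bounds = data.frame(id = ids,
                              lower_bound = model$reactions$lower_bound,
                              upper_bound = model$reactions$upper_bound,
                              stringsAsFactors = FALSE),
    growth_min = growth_min,
    effective_floor = floor_eff,
    baseline_growth = baseline,
    final_growth = final_growth,
    final_doubling_time_h = if (final_growth > 0) 1 / final_growth else NA_real_,
    n_fba_solves = n_solves,
    warnings = warn
  ), class = "integration_report")
  list(model = model, report = report)
}

#' @export
print.integration_report <- function(x, ...) {
  cat("<integration_report> sample:", x$sample_id, "\n")
  tab <- table(factor(x$disposition,
                      levels = c("media_locked", "essential_locked",
                                 "andor_skipped", "genes_missing",
                                 "constrained", "reopened")))
  for (nm in names(tab)) cat(sprintf("  %-16s %5d\n", nm, tab[[nm]]))
  cat(sprintf("  growth floor %.6g; final growth %.6g", x$growth_min,
              x$final_growth))
  if (!is.na(x$final_doubling_time_h))
    cat(sprintf(" (doubling time %.2f h)", x$final_doubling_time_h))
  cat("\n  FBA solves:", x$n_fba_solves, "\n")
  if (length(x$warnings)) cat("  warning:", x$warnings, "\n")
  invisible(x)
}

#' @export
summary.integration_report <- function(object, ...) {
  print(object)
  if (length(object$reopened))
    cat("  reopened:", paste(object$reopened, collapse = ", "), "\n")
  invisible(object)
}

#' Write an integration report to JSON
#'
#' @param report An `integration_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_integration_report <- function(report, path) {
  jsonlite::write_json(list(
    sample_id = report$sample_id,
    disposition = as.list(report$disposition),
    reopened = report$reopened,
    growth_min = report$growth_min,
    baseline_growth = report$baseline_growth,
    final_growth = report$final_growth,
    final_doubling_time_h = report$final_doubling_time_h,
    n_fba_solves = report$n_fba_solves,
    warnings = report$warnings,
    provenance = list(
      package = paste0("gemflux ", as.character(utils::packageVersion("gemflux"))),
      solver = "internal two-phase simplex")
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "list")
  invisible(path)
}
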