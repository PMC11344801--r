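#' Construct a metabolic model
#'
#' The in-memory representation of a constraint-based (stoichiometric) model.
#' Reactions are kept in the order given, and that document order is the
#' canonical iteration order for every order-sensitive operation downstream
#' (sequential expression integration in particular).
#'
#' @param id Model identifier.
#' @param reactions Data frame with columns `id`, `lower_bound`, `upper_bound`,
#'   `subsystem`, `gpr` (rule text; `""` for unannotated reactions).
#' @param stoichiometry List (one element per reaction, same order) of named
#'   numeric vectors, metabolite id -> signed coefficient (negative consumed).
#' @param metabolites Data frame with columns `id`, `compartment`.
#' @param objective_reaction_id Id of the biomass (objective) reaction.
#' @param default_bound Magnitude of the unconstrained flux bound
#'   (mmol/gDW/h), conventionally 1000.
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(id, reactions, stoichiometry, metabolites,
                            objective_reaction_id, default_bound = 1000) {
  stopifnot(is.data.frame(reactions),
            all(c("id", "lower_bound", "upper_bound", "subsystem", "gpr")
                %in% names(reactions)),
            length(stoichiometry) == nrow(reactions))
  reactions$id <- as.character(reactions$id)
  reactions$gpr <- as.character(reactions$gpr)
  reactions$subsystem <- as.character(reactions$subsystem)
  rownames(reactions) <- NULL
  gpr_rules <- lapply(reactions$gpr, parse_gpr)
  genes <- unique(unlist(lapply(gpr_rules, `[[`, "genes"), use.names = FALSE))
  if (is.null(genes)) genes <- character(0)
  model <- structure(list(
    id = id,
    reactions = reactions,
    stoichiometry = stoichiometry,
    metabolites = metabolites,
    genes = genes,
    gpr_rules = gpr_rules,
    objective_reaction_id = objective_reaction_id,
    default_bound = default_bound,
    media_locked = character(0),
    media_name = NULL
  ), class = "metabolic_model")
  validate_model(model)
  model
}

validate_model <- function(model) {
  rxn <- model$reactions
  if (anyDuplicated(rxn$id))
    stop("reaction ids are not unique: ",
         paste(unique(rxn$id[duplicated(rxn$id)]), collapse = ", "))
  if (!model$objective_reaction_id %in% rxn$id)
    stop("objective reaction '", model$objective_reaction_id,
         "' is not in the model")
  bad <- which(rxn$lower_bound > rxn$upper_bound)
  if (length(bad))
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rxn$id[bad], collapse = ", "))
  mets <- unique(unlist(lapply(model$stoichiometry, names), use.names = FALSE))
  missing_met <- setdiff(mets, model$metabolites$id)
  if (length(missing_met))
    stop("stoichiometry references unknown metabolite(s): ",
         paste(missing_met, collapse = ", "))
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions),
      " (", sum(exchange_reactions(x)), " exchange)\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites), "\n", sep = "")
  cat("  genes:       ", length(x$genes), "\n", sep = "")
  cat("  objective:   ", x$objective_reaction_id, "\n", sep = "")
  if (length(x$media_locked))
    cat("  media:       ", x$media_name %||% "(unnamed)", " (",
        length(x$media_locked), " exchange(s) locked)\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Which reactions are exchange reactions?
#'
#' An exchange (boundary) reaction involves exactly one metabolite; by the
#' COBRA sign convention negative flux through it is uptake.
#'
#' @param model A `metabolic_model`.
#' @return Logical vector along the model's reactions.
#' @export
exchange_reactions <- function(model) {
  vapply(model$stoichiometry, function(s) length(s) == 1L, logical(1))
}

reaction_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction id: ", reaction_id)
  i
}

#' Get or set the bounds of one reaction
#'
#' @param model A `metabolic_model`.
#' @param reaction_id Reaction id.
#' @return `reaction_bounds` returns `c(lower, upper)`.
#' @export
reaction_bounds <- function(model, reaction_id) {
  i <- reaction_index(model, reaction_id)
  c(lower = model$reactions$lower_bound[i],
    upper = model$reactions$upper_bound[i])
}

#' @rdname reaction_bounds
#' @param lower,upper New bounds (fluxes, mmol/gDW/h).
#' @return `set_reaction_bounds` returns the modified model.
#' @export
set_reaction_bounds <- function(model, reaction_id, lower, upper) {
  if (lower > upper) stop("lower bound exceeds upper bound for ", reaction_id)
  i <- reaction_index(model, reaction_id)
  model$reactions$lower_bound[i] <- lower
  model$reactions$upper_bound[i] <- upper
  model
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @return Dense numeric matrix, metabolites x reactions.
#' @export
stoichiometric_matrix <- function(model) {
  S <- matrix(0, nrow = nrow(model$metabolites), ncol = nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  for (j in seq_along(model$stoichiometry)) {
    s <- model$stoichiometry[[j]]
    S[names(s), j] <- s
  }
  S
}

#' Census of gene-protein-reaction rule categories
#'
#' Classifies every reaction's GPR rule and tabulates the counts the model
#' documentation usually reports: one-gene rules, isoenzyme (`or`) rules,
#' subunit (`and`) rules, mixed (`andor`) rules, and the annotated fraction.
#'
#' @param model A `metabolic_model`.
#' @return An object of class `rule_census`: a list of counts
#'   (`n_reactions`, `n_genes`, `n_annotated`, `n_one_gene`, `n_or`, `n_and`,
#'   `n_andor`) plus `fraction_annotated`.
#' @export
summarize_rules <- function(model) {
  cats <- vapply(model$gpr_rules, `[[`, character(1), "category")
  n <- c(n_reactions = nrow(model$reactions),
         n_genes = length(model$genes),
         n_annotated = sum(cats != "none"),
         n_one_gene = sum(cats == "one-gene"),
         n_or = sum(cats == "or"),
         n_and = sum(cats == "and"),
         n_andor = sum(cats == "andor"))
  out <- c(as.list(n), list(
    fraction_annotated = if (n[["n_reactions"]] > 0)
      n[["n_annotated"]] / n[["n_reactions"]] else 0
  ))
  structure(out, class = "rule_census")
}

#' @export
print.rule_census <- function(x, ...) {
  cat("GPR rule census\n")
  cat(sprintf("  reactions         %6d\n", x$n_reactions))
  cat(sprintf("  genes             %6d\n", x$n_genes))
  cat(sprintf("  annotated         %6d  (%.1f%%)\n",
              x$n_annotated, 100 * x$fraction_annotated))
  cat(sprintf("  one-gene          %6d\n", x$n_one_gene))
  cat(sprintf("  'or' (isoenzyme)  %6d\n", x$n_or))
  cat(sprintf("  'and' (subunit)   %6d\n", x$n_and))
  cat(sprintf("  'andor' (mixed)   %6d\n", x$n_andor))
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  print(object)
  cat("\n")
  print(summarize_rules(object))
  invisible(object)
}
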