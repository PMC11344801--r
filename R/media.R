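#' Define a growth medium
#'
#' A medium is a named set of exchange-reaction bounds (mmol/gDW/h). By the
#' COBRA sign convention a negative lower bound on an exchange reaction
#' permits uptake of its metabolite; exchanges not listed in the medium have
#' uptake closed when the medium is applied.
#'
#' @param entries Named list, exchange reaction id -> numeric `c(lb, ub)`.
#' @param name Medium name (e.g. `"DMEM"`).
#' @return An object of class `media_definition`.
#' @export
media_definition <- function(entries, name = "medium") {
  stopifnot(is.list(entries), length(names(entries)) == length(entries))
  for (id in names(entries)) {
    b <- as.numeric(entries[[id]])
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      stop("invalid bounds for media entry '", id, "'")
    entries[[id]] <- b
  }
  structure(list(name = name, entries = entries), class = "media_definition")
}

#' Read a medium from YAML or JSON
#'
#' Expected layout: `{name: DMEM, entries: {EX_glc: [-10, 0], ...}}`.
#'
#' @param path File path (`.yml`/`.yaml`/`.json`).
#' @return A `media_definition`.
#' @export
read_media <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  entries <- raw$entries
  if (is.data.frame(entries)) entries <- as.list(entries)
  media_definition(entries = lapply(entries, as.numeric),
                   name = raw$name %||% "medium")
}

#' @export
print.media_definition <- function(x, ...) {
  cat("<media_definition> ", x$name, ": ", length(x$entries),
      " exchange bound(s)\n", sep = "")
  invisible(x)
}

#' Apply a medium to a model
#'
#' Exchange reactions listed in the medium receive exactly the specified
#' bounds; every other exchange reaction has its uptake closed (lower bound
#' raised to 0) while secretion keeps its existing bound. Internal reactions
#' are untouched. The applied exchange ids are recorded on the model as
#' media-locked, which exempts them from expression-derived constraints later.
#'
#' @param model A `metabolic_model`.
#' @param media A `media_definition`.
#' @return The constrained model.
#' @export
apply_media <- function(model, media) {
  stopifnot(inherits(media, "media_definition"))
  is_ex <- exchange_reactions(model)
  ids <- model$reactions$id
  unknown <- setdiff(names(media$entries), ids)
  if (length(unknown))
    stop("media entries name unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  not_ex <- names(media$entries)[!is_ex[match(names(media$entries), ids)]]
  if (length(not_ex))
    stop("media entries are not exchange reactions: ",
         paste(not_ex, collapse = ", "))
  for (id in names(media$entries)) {
    b <- media$entries[[id]]
    model <- set_reaction_bounds(model, id, b[1], b[2])
  }
  close_idx <- which(is_ex & !ids %in% names(media$entries))
  for (i in close_idx) {
    if (model$reactions$lower_bound[i] < 0)
      model$reactions$lower_bound[i] <- 0
  }
  model$media_locked <- names(media$entries)
  model$media_name <- media$name
  model
}

#' Estimate undefined serum components by essentiality-directed reopening
#'
#' Culture media containing serum (FBS) are chemically under-defined, so a
#' medium built from the named ingredients alone can starve the model. This
#' procedure reconstructs the missing components greedily: while the FBA
#' optimum is below `growth_floor`, each candidate closed exchange is
#' temporarily restored to default bounds (`-default_bound`, or 0 if it was
#' irreversible at load, to `+default_bound`) and the exchange whose reopening
#' raises the optimum most is permanently reopened (ties broken by canonical
#' reaction order). The loop stops when the floor is met or no candidate
#' improves growth.
#'
#' @param model A media-constrained `metabolic_model`.
#' @param growth_floor Minimum acceptable growth rate (g/gDW/h).
#' @param candidates Exchange reaction ids to consider; default all closed
#'   non-media exchanges.
#' @return An object of class `serum_estimate`: list with `reopened` (ordered
#'   ids), `rationale` (data frame of per-step growth before/after),
#'   `satisfied` (did the final optimum reach the floor?), `final_growth`,
#'   and `model` (the model with the reopened bounds applied).
#' @export
estimate_serum_components <- function(model, growth_floor, candidates = NULL) {
  is_ex <- exchange_reactions(model)
  ids <- model$reactions$id
  if (is.null(candidates)) {
    candidates <- ids[is_ex & !ids %in% model$media_locked &
                        model$reactions$lower_bound >= 0]
  } else {
    overlap <- intersect(candidates, model$media_locked)
    if (length(overlap))
      stop("candidates overlap media-defined exchanges: ",
           paste(overlap, collapse = ", "))
    if (!all(candidates %in% ids[is_ex]))
      stop("candidates must be exchange reactions")
  }
  reopened <- character(0)
  steps <- list()
  current <- fba(model)$objective_value
  if (is.na(current)) current <- 0
  while (current < growth_floor && length(candidates)) {
    best <- NULL; best_val <- current
    for (cid in candidates) {  # candidate order = canonical order (tie-break)
      trial <- reopen_exchange(model, cid)
      val <- fba(trial)$objective_value
      if (!is.na(val) && val > best_val + 1e-9) {
        best <- cid; best_val <- val
      }
    }
    if (is.null(best)) break
    steps[[length(steps) + 1L]] <- data.frame(
      reaction_id = best, growth_before = current, growth_after = best_val,
      stringsAsFactors = FALSE)
    model <- reopen_exchange(model, best)
    reopened <- c(reopened, best)
    candidates <- setdiff(candidates, best)
    current <- best_val
  }
  structure(list(
    reopened = reopened,
    rationale = if (length(steps)) do.call(rbind, steps) else
      data.frame(reaction_id = character(0), growth_before = numeric(0),
                 growth_after = numeric(0)),
    satisfied = current >= growth_floor,
    final_growth = current,
    model = model
  ), class = "serum_estimate")
}

reopen_exchange <- function(model, reaction_id) {
  set_reaction_bounds(model, reaction_id,
                      -model$default_bound, model$default_bound)
}

#' @export
print.serum_estimate <- function(x, ...) {
  cat("<serum_estimate> reopened ", length(x$reopened), " exchange(s); final growth ",
      format(x$final_growth, digits = 6),
      if (x$satisfied) " (floor met)\n" else " (floor NOT met)\n", sep = "")
  if (length(x$reopened)) cat("  ", paste(x$reopened, collapse = ", "), "\n")
  invisible(x)
}
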