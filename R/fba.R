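# Linear programming layer. All LP calls in the package funnel through
# solve_lp() so the solver backend can be swapped in one place; the backend
# is the in-package two-phase simplex (lp.R). Variables are shifted to the
# nonnegative orthant; optional >= side constraints gain surplus variables.

solve_lp <- function(obj, S, lb, ub, beq = NULL, geq = NULL, bgeq = NULL,
                     maximize = TRUE) {
  n <- length(obj)
  stopifnot(ncol(S) == n, length(lb) == n, length(ub) == n)
  if (is.null(beq)) beq <- rep(0, nrow(S))
  if (any(lb > ub)) return(list(status = "infeasible", value = NA_real_, x = NULL))
  shift <- lb
  A <- S
  b <- as.vector(beq - S %*% shift)
  u <- ub - lb
  cvec <- obj
  if (!is.null(geq)) {
    geq <- matrix(geq, ncol = n)
    bg <- as.vector(bgeq - geq %*% shift)
    n_surp <- nrow(geq)
    surp_cap <- as.vector(abs(geq) %*% u) + abs(bg) + 1
    A <- rbind(cbind(A, matrix(0, nrow(A), n_surp)),
               cbind(geq, -diag(n_surp)))
    b <- c(b, bg)
    u <- c(u, surp_cap)
    cvec <- c(cvec, rep(0, n_surp))
  }
  res <- lp_simplex(cvec, A, b, u, maximize = maximize)
  if (res$status != "optimal")
    return(list(status = res$status, value = NA_real_, x = NULL))
  x <- res$x[seq_len(n)] + shift
  list(status = "optimal", value = sum(obj * x), x = x)
}

#' Flux balance analysis
#'
#' Maximises flux through the model's objective (biomass) reaction subject to
#' steady-state mass balance `S v = 0` and the reaction bounds. With
#' `parsimonious = TRUE` a second LP minimises the total absolute flux while
#' holding the objective at its optimum (pFBA), which selects a
#' minimal-total-flux representative among alternate optima.
#'
#' @param model A `metabolic_model`.
#' @param parsimonious Run the secondary flux-minimisation step?
#' @return An object of class `flux_solution`: list with `objective_value`,
#'   `fluxes` (named numeric along the reactions), `status` (`"optimal"`,
#'   `"infeasible"` or `"unsolved"`) and `parsimonious`.
#' @examples
#' m <- make_toy_gem(toy_gem_spec(n_chains = 1, uptake_capacity = 5))$model
#' fba(m)$objective_value
#' @export
fba <- function(model, parsimonious = FALSE) {
  rxn <- model$reactions
  S <- stoichiometric_matrix(model)
  obj <- as.numeric(rxn$id == model$objective_reaction_id)
  sol <- solve_lp(obj, S, rxn$lower_bound, rxn$upper_bound, maximize = TRUE)
  if (sol$status != "optimal") {
    return(new_flux_solution(NA_real_, setNames(rep(NA_real_, nrow(rxn)), rxn$id),
                             sol$status, parsimonious = FALSE))
  }
  if (!parsimonious) {
    return(new_flux_solution(sol$value, setNames(sol$x, rxn$id), "optimal",
                             parsimonious = FALSE))
  }
  psol <- pfba_step(model, S, obj, sol$value)
  if (psol$status != "optimal") {
    # numerically tight optimum pinning can fail; fall back to the plain solution
    return(new_flux_solution(sol$value, setNames(sol$x, rxn$id), "optimal",
                             parsimonious = FALSE))
  }
  new_flux_solution(sol$value, setNames(psol$v, rxn$id), "optimal",
                    parsimonious = TRUE)
}

# minimise sum(|v|) subject to S v = 0, bounds, and obj'v = opt.
# Split v = p - n with p in [max(lb,0), max(ub,0)], n in [max(-ub,0), max(-lb,0)];
# those box bounds reproduce lb <= v <= ub exactly for any sign pattern.
pfba_step <- function(model, S, obj, opt) {
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- length(lb)
  # pin the objective with a >= row (an exact equality leaves the system with
  # zero slack, which the simplex backend cannot pivot through)
  sol <- solve_lp(obj = rep(1, 2 * n), S = cbind(S, -S),
                  lb = c(pmax(lb, 0), pmax(-ub, 0)),
                  ub = c(pmax(ub, 0), pmax(-lb, 0)),
                  geq = matrix(c(obj, -obj), nrow = 1),
                  bgeq = opt - 1e-9, maximize = FALSE)
  if (sol$status != "optimal") return(list(status = sol$status))
  list(status = "optimal", v = sol$x[seq_len(n)] - sol$x[n + seq_len(n)])
}

new_flux_solution <- function(objective_value, fluxes, status, parsimonious) {
  structure(list(objective_value = objective_value, fluxes = fluxes,
                 status = status, parsimonious = parsimonious),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      if (isTRUE(x$parsimonious)) "(parsimonious)" else "", "\n")
  if (x$status == "optimal")
    cat("  objective:", format(x$objective_value, digits = 7), "\n",
        "  non-zero fluxes:", sum(abs(x$fluxes) > 1e-9), "of",
        length(x$fluxes), "\n")
  invisible(x)
}
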