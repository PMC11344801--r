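# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdirs.

# two-chain model with capacities 2 and 3 (analytic optimum 5)
two_chain <- function(...) {
  make_toy_gem(toy_gem_spec(n_chains = 2, chain_length = 2,
                            uptake_capacity = c(2, 3), ...))
}

toy_media <- function(model, uptakes) {
  media_definition(setNames(lapply(uptakes, function(u) c(-u, 0)),
                            names(uptakes)),
                   name = "toy_medium")
}

# independent GPR oracle: translate the rule to an R boolean expression and
# evaluate it with base R, bypassing the package's tree walker
eval_gpr_oracle <- function(rule_text, states) {
  txt <- gsub("\\band\\b", "&&", rule_text, ignore.case = TRUE)
  txt <- gsub("\\bor\\b", "||", txt, ignore.case = TRUE)
  env <- list2env(as.list(states))
  genes <- setdiff(all.vars(parse(text = txt)[[1]]), ls(env))
  for (g in genes) assign(g, TRUE, envir = env)
  eval(parse(text = txt)[[1]], envir = env)
}

# independent replay of the sequential constrain/check/relax loop, written
# with explicit bookkeeping against fba() only (no calls into
# integrate_expression); used as the step-by-step oracle
replay_integration <- function(model, expression, growth_min,
                               essential_fraction = 0.01) {
  opt_of <- function(m) {
    v <- fba(m)$objective_value
    if (is.na(v)) 0 else v
  }
  base <- opt_of(model)
  floor_eff <- min(growth_min, base)
  reopened <- character(0)
  opts <- numeric(0)
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    if (rid %in% model$media_locked) next
    rule <- model$gpr_rules[[i]]
    if (!rule$category %in% c("one-gene", "or", "and")) next
    if (!all(rule$genes %in% names(expression$values))) next
    cur <- opt_of(model)
    closed <- set_reaction_bounds(model, rid, 0, 0)
    if (opt_of(closed) < essential_fraction * cur - 1e-12) next
    lo <- model$reactions$lower_bound[i]
    e <- expression$values[rule$genes]
    cap <- switch(rule$category, "one-gene" = unname(e), "or" = sum(e),
                  "and" = min(e))
    trial <- set_reaction_bounds(model, rid, if (lo < 0) -cap else 0, cap)
    if (opt_of(trial) < floor_eff - 1e-9) {
      reopened <- c(reopened, rid)
    } else {
      model <- trial
      opts <- c(opts, opt_of(model))
    }
  }
  list(reopened = reopened, final = opt_of(model), kept_opts = opts)
}
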