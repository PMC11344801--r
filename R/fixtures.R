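# Toy-model generator. The topology is deliberately simple -- parallel linear
# uptake -> conversion -> biomass chains -- so the FBA optimum has a closed
# form (sum over chains of the minimum capacity along the chain) and every
# downstream module can be tested against exact ground truth.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a toy genome-scale model
#'
#' @param n_chains Number of parallel linear chains feeding biomass.
#' @param chain_length Internal conversion steps per chain (>= 1).
#' @param uptake_capacity Uptake bound per chain (recycled), mmol/gDW/h.
#' @param internal_capacity Upper bound of internal conversions (recycled).
#' @param rule_categories GPR categories to cycle across the internal
#'   reactions: subset of `"one-gene"`, `"or"`, `"and"`, `"andor"`, `"none"`.
#' @param bottleneck Optional `list(reaction_id =, capacity =)` overriding one
#'   internal reaction's upper bound. Internal reactions are named
#'   `R<chain>_S<step>`, chain uptakes `EX_C<chain>`.
#' @param planted_essentials Gene ids to plant on a shared funnel reaction
#'   (every chain's product passes through it), making each individually
#'   essential. Fresh ids are appended to the generated gene pool.
#' @param reversible_steps Indices of internal steps made reversible
#'   (lower bound `-capacity`); default none.
#' @param seed Seed for any randomised choices (kept for reproducibility;
#'   generation is currently fully deterministic).
#' @return A `toy_gem_spec` list.
#' @export
toy_gem_spec <- function(n_chains = 2, chain_length = 2, uptake_capacity = 5,
                         internal_capacity = 10,
                         rule_categories = c("one-gene", "or", "and"),
                         bottleneck = NULL, planted_essentials = character(0),
                         reversible_steps = integer(0), seed = 1L) {
  stopifnot(n_chains >= 1, chain_length >= 1,
            all(uptake_capacity > 0), all(internal_capacity > 0))
  ok <- c("one-gene", "or", "and", "andor", "none")
  if (!all(rule_categories %in% ok))
    stop("unknown rule categories: ",
         paste(setdiff(rule_categories, ok), collapse = ", "))
  if (!is.null(bottleneck)) {
    if (!is.list(bottleneck) || is.null(bottleneck$reaction_id) ||
        is.null(bottleneck$capacity) || bottleneck$capacity <= 0)
      stop("bottleneck must be list(reaction_id =, capacity > 0)")
  }
  structure(list(n_chains = n_chains, chain_length = chain_length,
                 uptake_capacity = uptake_capacity,
                 internal_capacity = internal_capacity,
                 rule_categories = rule_categories, bottleneck = bottleneck,
                 planted_essentials = as.character(planted_essentials),
                 reversible_steps = reversible_steps, seed = seed),
            class = "toy_gem_spec")
}

#' Generate a toy genome-scale model with known ground truth
#'
#' Builds `n_chains` parallel linear pathways, each starting at an exchange
#' reaction (uptake negative, COBRA convention), passing through
#' `chain_length` internal conversions, and draining into a shared biomass
#' precursor consumed by the objective reaction. GPR rules are assigned to
#' internal reactions by cycling through the requested categories; when
#' essential genes are planted, all chains are funnelled through one extra
#' reaction carrying an `and` rule over those genes.
#'
#' @param spec A `toy_gem_spec`.
#' @return List with `model` (a `metabolic_model`) and `truth`: analytic
#'   optimum (`optimum`), per-chain capacities (`chain_capacity`), chain
#'   uptake exchange ids (`chain_exchanges`), internal reaction ids per chain
#'   (`chain_reactions`), planted `essential_genes`, `funnel_id` (or `NA`),
#'   and `gene_of` (gene -> reaction ids it appears in).
#' @export
make_toy_gem <- function(spec) {
  stopifnot(inherits(spec, "toy_gem_spec"))
  up <- rep_len(spec$uptake_capacity, spec$n_chains)
  cap <- matrix(rep_len(spec$internal_capacity,
                        spec$n_chains * spec$chain_length),
                nrow = spec$n_chains, byrow = TRUE)
  ids <- character(0); lb <- numeric(0); ub <- numeric(0)
  subsys <- character(0); gpr <- character(0); stoich <- list()
  mets <- character(0)
  gene_counter <- 0L
  next_genes <- function(k) {
    g <- paste0("G", gene_counter + seq_len(k))
    gene_counter <<- gene_counter + k
    g
  }
  cats <- rep_len(spec$rule_categories,
                  max(1L, spec$n_chains * spec$chain_length))
  add_rxn <- function(id, s, lo, hi, sub, rule) {
    ids <<- c(ids, id); lb <<- c(lb, lo); ub <<- c(ub, hi)
    subsys <<- c(subsys, sub); gpr <<- c(gpr, rule)
    stoich[[length(stoich) + 1L]] <<- s
    mets <<- union(mets, names(s))
  }
  ci <- 0L
  for (j in seq_len(spec$n_chains)) {
    m_prev <- sprintf("A%d_1", j)
    add_rxn(sprintf("EX_C%d", j), setNames(-1, m_prev), -up[j], 0,
            "Exchange/demand", "")
    for (k in seq_len(spec$chain_length)) {
      ci <- ci + 1L
      m_next <- if (k < spec$chain_length) sprintf("A%d_%d", j, k + 1) else "P"
      rule <- switch(cats[ci],
        "one-gene" = next_genes(1),
        "or" = paste(next_genes(2), collapse = " or "),
        "and" = paste(next_genes(2), collapse = " and "),
        "andor" = { g <- next_genes(3)
                    sprintf("(%s and %s) or %s", g[1], g[2], g[3]) },
        "none" = "")
      lo <- if (k %in% spec$reversible_steps) -cap[j, k] else 0
      add_rxn(sprintf("R%d_S%d", j, k),
              setNames(c(-1, 1), c(m_prev, m_next)),
              lo, cap[j, k], sprintf("Pathway %d", j), rule)
      m_prev <- m_next
    }
  }
  funnel_id <- NA_character_
  biomass_in <- "P"
  if (length(spec$planted_essentials)) {
    funnel_id <- "FUNNEL"
    add_rxn(funnel_id, c(P = -1, Q = 1), 0, 1000,
            "Biomass funnel",
            paste(spec$planted_essentials, collapse = " and "))
    biomass_in <- "Q"
  }
  add_rxn("BIOMASS", setNames(c(-1, 1), c(biomass_in, "BM")), 0, 1000,
          "Biomass", "")
  add_rxn("EX_BIOMASS", c(BM = -1), 0, 1000, "Exchange/demand", "")

  reactions <- data.frame(id = ids, lower_bound = lb, upper_bound = ub,
                          subsystem = subsys, gpr = gpr,
                          stringsAsFactors = FALSE)
  if (!is.null(spec$bottleneck)) {
    i <- match(spec$bottleneck$reaction_id, reactions$id)
    if (is.na(i))
      stop("bottleneck reaction '", spec$bottleneck$reaction_id,
           "' does not exist in the generated model")
    reactions$upper_bound[i] <- spec$bottleneck$capacity
    if (reactions$lower_bound[i] < 0)
      reactions$lower_bound[i] <- -spec$bottleneck$capacity
  }
  metabolites <- data.frame(id = mets, compartment = "c",
                            stringsAsFactors = FALSE)
  model <- metabolic_model(
    id = sprintf("toy_gem_%dx%d", spec$n_chains, spec$chain_length),
    reactions = reactions, stoichiometry = stoich, metabolites = metabolites,
    objective_reaction_id = "BIOMASS", default_bound = 1000)

  chain_capacity <- vapply(seq_len(spec$n_chains), function(j) {
    rids <- sprintf("R%d_S%d", j, seq_len(spec$chain_length))
    min(up[j], model$reactions$upper_bound[match(rids, model$reactions$id)])
  }, numeric(1))
  gene_of <- lapply(setNames(nm = model$genes), function(g)
    model$reactions$id[vapply(model$gpr_rules, function(r)
      g %in% r$genes, logical(1))])
  truth <- list(
    optimum = sum(chain_capacity),
    chain_capacity = chain_capacity,
    chain_exchanges = sprintf("EX_C%d", seq_len(spec$n_chains)),
    chain_reactions = lapply(seq_len(spec$n_chains), function(j)
      sprintf("R%d_S%d", j, seq_len(spec$chain_length))),
    essential_genes = spec$planted_essentials,
    funnel_id = funnel_id,
    gene_of = gene_of)
  list(model = model, truth = truth)
}

#' Generate a deterministic expression profile for a toy model
#'
#' `low_genes` receive `low_value` (below a chain's demand, so their
#' reactions bind once integrated), `high_genes` receive `high_value`, and
#' every other model gene sits at `base_level` with small Gaussian jitter.
#'
#' @param model A `metabolic_model`.
#' @param seed RNG seed (same seed, same profile).
#' @param high_genes,low_genes Disjoint subsets of the model genes.
#' @param base_level Background expression (log2(TPM+1) scale).
#' @param low_value,high_value Values for the planted sets.
#' @param jitter_sd Standard deviation of the background jitter.
#' @param sample_id Profile label.
#' @return An `expression_profile`.
#' @export
make_expression <- function(model, seed = 1L, high_genes = character(0),
                            low_genes = character(0), base_level = 5,
                            low_value = 0.5, high_value = 8,
                            jitter_sd = 0.1, sample_id = "toy_sample") {
  overlap <- intersect(high_genes, low_genes)
  if (length(overlap))
    stop("genes in both high and low sets: ", paste(overlap, collapse = ", "))
  bad <- setdiff(c(high_genes, low_genes), model$genes)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  vals <- with_seed(seed, {
    v <- pmax(0, base_level + stats::rnorm(length(model$genes), 0, jitter_sd))
    names(v) <- model$genes
    v[high_genes] <- high_value
    v[low_genes] <- low_value
    v
  })
  expression_profile(vals, sample_id)
}

#' Generate a synthetic gene-dependency dataset
#'
#' Emulates a CRISPR dependency screen over two groups of cell lines:
#' essential genes score around 0.9, others around 0.1 (clipped Gaussians,
#' truncated to `[0, 1]`). Group-specific essential sets emulate a subtype
#' contrast recoverable by [dependency_delta()].
#'
#' @param model A `metabolic_model` (supplies the gene universe).
#' @param seed RNG seed.
#' @param essential_genes Genes essential in every line.
#' @param noise_sd Gaussian noise SD (>= 0); 0 gives exactly 0.9/0.1.
#' @param n_lines Cell lines per group.
#' @param group_essentials Named list of extra per-group essential genes,
#'   e.g. `list(low = c("G1"), high = character(0))`.
#' @return A `dependency_dataset` with groups named after
#'   `names(group_essentials)` (default `"low"` and `"high"`).
#' @export
make_dependency <- function(model, seed = 1L, essential_genes = character(0),
                            noise_sd = 0.05, n_lines = 3,
                            group_essentials = list(low = character(0),
                                                    high = character(0))) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  bad <- setdiff(c(essential_genes, unlist(group_essentials)), model$genes)
  if (length(bad)) stop("unknown gene(s): ", paste(bad, collapse = ", "))
  groups <- lapply(seq_along(group_essentials), function(gi)
    sprintf("%s_L%d", names(group_essentials)[gi], seq_len(n_lines)))
  names(groups) <- names(group_essentials)
  lines <- unlist(groups, use.names = FALSE)
  scores <- with_seed(seed, {
    m <- matrix(NA_real_, nrow = length(lines), ncol = length(model$genes),
                dimnames = list(lines, model$genes))
    for (g in names(groups)) {
      ess <- union(essential_genes, group_essentials[[g]])
      for (ln in groups[[g]]) {
        mu <- ifelse(model$genes %in% ess, 0.9, 0.1)
        m[ln, ] <- pmin(1, pmax(0, mu + stats::rnorm(length(mu), 0, noise_sd)))
      }
    }
    m
  })
  dependency_dataset(scores, groups)
}

#' Build planted-effect flux tables for two groups
#'
#' A fixture for the differential-flux criteria: both groups share a base
#' flux vector; `planted` reactions get their group-"high" mean shifted by
#' the named relative effect. With `noise_sd = 0` the planted reactions are
#' exactly the flagged set for the default criteria, provided base fluxes
#' exceed the magnitude threshold and effects exceed the relative threshold.
#'
#' @param model A `metabolic_model`.
#' @param planted Named numeric vector, reaction id -> relative effect (e.g.
#'   `c(R1_S1 = 0.5)` raises the high-group mean by 50%).
#' @param base_flux Baseline flux for every internal reaction.
#' @param n_per_group Samples per group.
#' @param noise_sd Gaussian noise SD.
#' @param seed RNG seed.
#' @return List of two `group_flux_table`s, `low` and `high`.
#' @export
make_flux_groups <- function(model, planted = numeric(0), base_flux = 1,
                             n_per_group = 3, noise_sd = 0, seed = 1L) {
  ids <- model$reactions$id
  bad <- setdiff(names(planted), ids)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "))
  base <- setNames(rep(base_flux, length(ids)), ids)
  with_seed(seed, {
    mk <- function(mu) {
      m <- replicate(n_per_group, mu + stats::rnorm(length(mu), 0, noise_sd))
      rownames(m) <- ids
      colnames(m) <- paste0("s", seq_len(n_per_group))
      m
    }
    hi <- base
    hi[names(planted)] <- hi[names(planted)] * (1 + planted)
    list(low = group_flux_table("low", mk(base)),
         high = group_flux_table("high", mk(hi)))
  })
}

#' Write a complete fixture bundle to a directory
#'
#' Emits the SBML model, an expression TSV (genes x samples), a media YAML
#' opening the chain uptakes, a thresholds YAML, a dependency CSV and a
#' ground-truth JSON -- the full set of inputs the pipeline consumes, at toy
#' scale.
#'
#' @param dir Output directory (created if needed).
#' @param spec A `toy_gem_spec`.
#' @param doubling_time_h Doubling time written to the thresholds file.
#' @param seed RNG seed for the expression/dependency components.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(dir,
                                 spec = toy_gem_spec(
                                   n_chains = 2, chain_length = 2,
                                   uptake_capacity = c(2, 3),
                                   planted_essentials = "ESS1"),
                                 doubling_time_h = 1, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_toy_gem(spec)
  paths <- c(model = file.path(dir, "model.xml"),
             expression = file.path(dir, "expression.tsv"),
             media = file.path(dir, "media.yml"),
             thresholds = file.path(dir, "thresholds.yml"),
             dependency = file.path(dir, "dependency.csv"),
             truth = file.path(dir, "ground_truth.json"))
  write_sbml_model(fx$model, paths[["model"]])
  prof <- make_expression(fx$model, seed = seed)
  mat <- matrix(prof$values, ncol = 1,
                dimnames = list(names(prof$values), prof$sample_id))
  utils::write.table(data.frame(gene = rownames(mat), mat,
                                check.names = FALSE),
                     paths[["expression"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  media <- lapply(fx$truth$chain_exchanges, function(id)
    c(-rep_len(spec$uptake_capacity, spec$n_chains)[
      match(id, fx$truth$chain_exchanges)], 0))
  names(media) <- fx$truth$chain_exchanges
  yaml::write_yaml(list(name = "toy_medium", entries = media),
                   paths[["media"]])
  yaml::write_yaml(setNames(list(doubling_time_h), prof$sample_id),
                   paths[["thresholds"]])
  dep <- make_dependency(fx$model, seed = seed,
                         essential_genes = spec$planted_essentials)
  utils::write.csv(data.frame(cell_line = rownames(dep$scores), dep$scores,
                              check.names = FALSE),
                   paths[["dependency"]], row.names = FALSE)
  jsonlite::write_json(fx$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
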