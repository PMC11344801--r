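# SBML Level 3 (FBC v2) reader/writer. Subsystems travel in the SBML groups
# package, gene ids in fbc:geneProduct labels, bounds as shared fbc parameters
# -- the serialisation conventions used by COBRA-family toolchains, so models
# written here are readable elsewhere and vice versa.

SBML_NS <- c(
  sbml   = "http://www.sbml.org/sbml/level3/version1/core",
  fbc    = "http://www.sbml.org/sbml/level3/version1/fbc/version2",
  groups = "http://www.sbml.org/sbml/level3/version1/groups/version1"
)

sbml_id <- function(prefix, id) {
  safe <- gsub("[^A-Za-z0-9_]", "_", id)
  paste0(prefix, safe)
}

strip_prefix <- function(x, prefix) {
  ifelse(startsWith(x, prefix), substring(x, nchar(prefix) + 1L), x)
}

#' Write a model to SBML Level 3 with the FBC extension
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_sbml_model()]
#' @export
write_sbml_model <- function(model, path) {
  rxn <- model$reactions
  bounds <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  par_ids <- paste0("FB_", seq_along(bounds))
  par_of <- function(v) par_ids[match(v, bounds)]

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub('"', "&quot;", x, fixed = TRUE)
  }
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<sbml xmlns="%s" xmlns:fbc="%s" xmlns:groups="%s" ',
                   'level="3" version="1" fbc:required="false" ',
                   'groups:required="false">'),
            SBML_NS[["sbml"]], SBML_NS[["fbc"]], SBML_NS[["groups"]]),
    sprintf('  <model id="%s" fbc:strict="true">', esc(sbml_id("", model$id)))
  )
  comps <- unique(model$metabolites$compartment)
  out <- c(out, "    <listOfCompartments>",
           sprintf('      <compartment id="%s" constant="true"/>', esc(comps)),
           "    </listOfCompartments>")
  out <- c(out, "    <listOfSpecies>",
           sprintf(paste0('      <species id="%s" compartment="%s" ',
                          'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
                          'constant="false"/>'),
                   vapply(model$metabolites$id, sbml_id, "", prefix = "M_"),
                   esc(model$metabolites$compartment)),
           "    </listOfSpecies>")
  out <- c(out, "    <listOfParameters>",
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   par_ids, format(bounds, digits = 17, scientific = FALSE)),
           "    </listOfParameters>")

  out <- c(out, "    <listOfReactions>")
  for (j in seq_len(nrow(rxn))) {
    s <- model$stoichiometry[[j]]
    out <- c(out, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">'),
      sbml_id("R_", rxn$id[j]),
      if (rxn$lower_bound[j] < 0) "true" else "false",
      par_of(rxn$lower_bound[j]), par_of(rxn$upper_bound[j])))
    reac <- s[s < 0]; prod <- s[s > 0]
    if (length(reac)) out <- c(out, "        <listOfReactants>",
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              vapply(names(reac), sbml_id, "", prefix = "M_"),
              format(-unname(reac), digits = 15)),
      "        </listOfReactants>")
    if (length(prod)) out <- c(out, "        <listOfProducts>",
      sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
              vapply(names(prod), sbml_id, "", prefix = "M_"),
              format(unname(prod), digits = 15)),
      "        </listOfProducts>")
    tree <- model$gpr_rules[[j]]$structure
    if (!is.null(tree)) {
      out <- c(out, "        <fbc:geneProductAssociation>",
               gpr_to_sbml(tree, indent = "          "),
               "        </fbc:geneProductAssociation>")
    }
    out <- c(out, "      </reaction>")
  }
  out <- c(out, "    </listOfReactions>")

  out <- c(out,
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            sbml_id("R_", model$objective_reaction_id)),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>")

  if (length(model$genes)) {
    out <- c(out, "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
              vapply(model$genes, sbml_id, "", prefix = "G_"), esc(model$genes)),
      "    </fbc:listOfGeneProducts>")
  }

  subsys <- split(rxn$id, rxn$subsystem)
  subsys <- subsys[nzchar(names(subsys))]
  if (length(subsys)) {
    out <- c(out, "    <groups:listOfGroups>")
    for (k in seq_along(subsys)) {
      out <- c(out,
        sprintf('      <groups:group groups:id="grp_%d" groups:kind="partonomy" groups:name="%s">',
                k, esc(names(subsys)[k])),
        "        <groups:listOfMembers>",
        sprintf('          <groups:member groups:idRef="%s"/>',
                vapply(subsys[[k]], sbml_id, "", prefix = "R_")),
        "        </groups:listOfMembers>",
        "      </groups:group>")
    }
    out <- c(out, "    </groups:listOfGroups>")
  }
  out <- c(out, "  </model>", "</sbml>")
  writeLines(out, path)
  invisible(path)
}

gpr_to_sbml <- function(node, indent) {
  if (is.character(node)) {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                   indent, sbml_id("G_", node)))
  }
  c(sprintf("%s<fbc:%s>", indent, node$op),
    unlist(lapply(node$args, gpr_to_sbml, indent = paste0(indent, "  "))),
    sprintf("%s</fbc:%s>", indent, node$op))
}

#' Read an SBML Level 3 (FBC) model
#'
#' Parses species, reaction stoichiometry, flux bounds (through the FBC
#' parameter indirection), gene-product associations and the active objective.
#' Reaction order follows document order; subsystem tags are taken from SBML
#' `groups` when present. Conventional `R_`/`M_`/`G_` id prefixes are stripped;
#' gene products are reported by their `fbc:label` when one is set.
#'
#' @param path Path to an SBML file.
#' @param default_bound Bound magnitude treated as "unconstrained"
#'   (mmol/gDW/h) for downstream relaxation steps.
#' @return A `metabolic_model`.
#' @export
read_sbml_model <- function(path, default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML file '", path,
                                           "': ", conditionMessage(e)))
  ns <- SBML_NS
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("SBML parse error: no <model> element in ", path)
  model_id <- xml2::xml_attr(mdl, "id")
  if (is.na(model_id)) model_id <- "model"

  sp <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  sp_ids_raw <- xml2::xml_attr(sp, "id")
  metabolites <- data.frame(
    id = strip_prefix(sp_ids_raw, "M_"),
    compartment = xml2::xml_attr(sp, "compartment"),
    stringsAsFactors = FALSE)
  met_of <- setNames(metabolites$id, sp_ids_raw)

  pars <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter", ns)
  par_val <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                      xml2::xml_attr(pars, "id"))

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_ids <- xml2::xml_attr(gp, "fbc:id", ns = ns)
  gp_plain <- xml2::xml_attr(gp, "id")
  gp_ids[is.na(gp_ids)] <- gp_plain[is.na(gp_ids)]
  gp_lab <- xml2::xml_attr(gp, "fbc:label", ns = ns)
  gene_label <- setNames(ifelse(is.na(gp_lab) | !nzchar(gp_lab),
                                strip_prefix(gp_ids, "G_"), gp_lab), gp_ids)

  rxn_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction", ns)
  if (length(rxn_nodes) == 0L)
    stop("SBML parse error: model has no reactions")
  n <- length(rxn_nodes)
  ids <- character(n); lbv <- numeric(n); ubv <- numeric(n)
  gprs <- character(n); stoich <- vector("list", n)
  for (j in seq_len(n)) {
    node <- rxn_nodes[[j]]
    rid_raw <- xml2::xml_attr(node, "id")
    ids[j] <- strip_prefix(rid_raw, "R_")
    lb_ref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = ns)
    if (is.na(lb_ref) || is.na(ub_ref) ||
        is.na(par_val[lb_ref]) || is.na(par_val[ub_ref]))
      stop("SBML parse error: reaction '", rid_raw,
           "' lacks resolvable fbc flux bounds")
    lbv[j] <- par_val[[lb_ref]]; ubv[j] <- par_val[[ub_ref]]
    s <- numeric(0)
    for (ref in xml2::xml_find_all(node, "./sbml:listOfReactants/sbml:speciesReference", ns)) {
      m <- met_of[[xml2::xml_attr(ref, "species")]]
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) -
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(node, "./sbml:listOfProducts/sbml:speciesReference", ns)) {
      m <- met_of[[xml2::xml_attr(ref, "species")]]
      s[m] <- (if (m %in% names(s)) s[[m]] else 0) +
        as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    stoich[[j]] <- s[s != 0]
    assoc <- xml2::xml_find_first(node, "./fbc:geneProductAssociation/*", ns)
    gprs[j] <- if (inherits(assoc, "xml_missing")) "" else
      sbml_gpr_text(assoc, gene_label)
  }

  obj_node <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  if (inherits(obj_node, "xml_missing"))
    stop("SBML parse error: no active flux objective defined")
  objective_id <- strip_prefix(xml2::xml_attr(obj_node, "fbc:reaction", ns = ns), "R_")

  subsystem <- setNames(rep("", n), ids)
  for (grp in xml2::xml_find_all(mdl, ".//groups:listOfGroups/groups:group", ns)) {
    gname <- xml2::xml_attr(grp, "groups:name", ns = ns)
    members <- xml2::xml_find_all(grp, "./groups:listOfMembers/groups:member", ns)
    mids <- strip_prefix(xml2::xml_attr(members, "groups:idRef", ns = ns), "R_")
    subsystem[mids[mids %in% ids]] <- gname
  }

  metabolic_model(
    id = model_id,
    reactions = data.frame(id = ids, lower_bound = lbv, upper_bound = ubv,
                           subsystem = unname(subsystem), gpr = gprs,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    metabolites = metabolites,
    objective_reaction_id = objective_id,
    default_bound = default_bound)
}

sbml_gpr_text <- function(node, gene_label) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
    lbl <- if (gid %in% names(gene_label)) gene_label[[gid]] else strip_prefix(gid, "G_")
    return(lbl)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, function(k) {
    txt <- sbml_gpr_text(k, gene_label)
    if (xml2::xml_name(k) %in% c("and", "or")) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = paste0(" ", nm, " "))
}
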