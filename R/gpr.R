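#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean gene association of the form `"G1 and (G2 or G3)"` into a
#' structured rule. Operators `and`/`or` are case-insensitive; gene identifiers
#' are bare whitespace-delimited tokens; parentheses group as usual. Duplicate
#' gene ids are collapsed before the rule category is assigned, so `"G1 or G1"`
#' classifies as a one-gene rule.
#'
#' The category describes which operators occur in the rule:
#' \describe{
#'   \item{`none`}{empty rule, no gene association.}
#'   \item{`one-gene`}{a single gene, no operators.}
#'   \item{`or`}{two or more genes joined only by `or` (isoenzymes).}
#'   \item{`and`}{two or more genes joined only by `and` (complex subunits).}
#'   \item{`andor`}{both operators occur.}
#' }
#'
#' @param rule_text Character scalar; `""` and `NA` give the empty rule.
#' @return An object of class `gpr_rule`: a list with elements `category`,
#'   `genes` (unique ids in order of first appearance), and `structure`
#'   (the expression tree; a gene id leaf or `list(op =, args =)`).
#' @examples
#' parse_gpr("(G1 and G2) or G3")$category
#' parse_gpr("G1 or G2 or G1")$genes
#' @export
parse_gpr <- function(rule_text) {
  if (length(rule_text) != 1L)
    stop("rule_text must be a single string")
  if (is.na(rule_text) || !nzchar(trimws(rule_text))) {
    return(new_gpr_rule(category = "none", genes = character(0), structure = NULL))
  }
  toks <- gpr_tokenize(rule_text)
  parsed <- gpr_parse_or(toks, 1L)
  if (parsed$pos <= length(toks))
    stop("GPR parse error: unexpected token '", toks[parsed$pos],
         "' in rule: ", rule_text)
  structure_tree <- parsed$node
  genes <- unique(gpr_tree_genes(structure_tree))
  ops <- gpr_tree_ops(structure_tree)
  category <- if (length(genes) == 1L) {
    "one-gene"
  } else if (all(ops == "or")) {
    "or"
  } else if (all(ops == "and")) {
    "and"
  } else {
    "andor"
  }
  new_gpr_rule(category = category, genes = genes, structure = structure_tree)
}

new_gpr_rule <- function(category, genes, structure) {
  structure(list(category = category, genes = genes, structure = structure),
            class = "gpr_rule")
}

gpr_tokenize <- function(text) {
  # pad parentheses so bare strsplit on whitespace suffices
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  bad <- grepl("[()]", toks) & !toks %in% c("(", ")")
  if (any(bad)) stop("GPR parse error: malformed token '", toks[bad][1], "'")
  toks
}

# recursive-descent: or_expr := and_expr ('or' and_expr)*
gpr_parse_or <- function(toks, pos) {
  left <- gpr_parse_and(toks, pos)
  args <- list(left$node)
  pos <- left$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "or") {
    nxt <- gpr_parse_and(toks, pos + 1L)
    args <- c(args, list(nxt$node))
    pos <- nxt$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  list(node = node, pos = pos)
}

gpr_parse_and <- function(toks, pos) {
  left <- gpr_parse_atom(toks, pos)
  args <- list(left$node)
  pos <- left$pos
  while (pos <= length(toks) && tolower(toks[pos]) == "and") {
    nxt <- gpr_parse_atom(toks, pos + 1L)
    args <- c(args, list(nxt$node))
    pos <- nxt$pos
  }
  node <- if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  list(node = node, pos = pos)
}

gpr_parse_atom <- function(toks, pos) {
  if (pos > length(toks))
    stop("GPR parse error: unexpected end of rule")
  tok <- toks[pos]
  if (tok == "(") {
    inner <- gpr_parse_or(toks, pos + 1L)
    if (inner$pos > length(toks) || toks[inner$pos] != ")")
      stop("GPR parse error: unbalanced parentheses")
    return(list(node = inner$node, pos = inner$pos + 1L))
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or"))
    stop("GPR parse error: unexpected token '", tok, "'")
  list(node = tok, pos = pos + 1L)
}

gpr_tree_genes <- function(node) {
  if (is.null(node)) return(character(0))
  if (is.character(node)) return(node)
  unlist(lapply(node$args, gpr_tree_genes), use.names = FALSE)
}

gpr_tree_ops <- function(node) {
  if (is.null(node) || is.character(node)) return(character(0))
  c(node$op, unlist(lapply(node$args, gpr_tree_ops), use.names = FALSE))
}

#' Render a GPR rule back to text
#'
#' Inverse of [parse_gpr()] up to whitespace and redundant parentheses;
#' `parse_gpr(format(rule))` reproduces the same category, gene list and
#' evaluation behaviour.
#'
#' @param x A `gpr_rule`.
#' @param ... Unused.
#' @return Character scalar (empty string for the `none` category).
#' @export
format.gpr_rule <- function(x, ...) {
  gpr_render(x$structure)
}

gpr_render <- function(node) {
  if (is.null(node)) return("")
  if (is.character(node)) return(node)
  parts <- vapply(node$args, function(a) {
    txt <- gpr_render(a)
    if (!is.character(a)) paste0("(", txt, ")") else txt
  }, character(1))
  paste(parts, collapse = paste0(" ", node$op, " "))
}

#' @export
print.gpr_rule <- function(x, ...) {
  cat("<gpr_rule> category:", x$category,
      "| genes:", if (length(x$genes)) paste(x$genes, collapse = ", ") else "(none)",
      "\n")
  if (!is.null(x$structure)) cat("  ", format(x), "\n", sep = "")
  invisible(x)
}

#' Evaluate a GPR rule under a gene knockout state
#'
#' @param rule A `gpr_rule`.
#' @param gene_states Named logical vector; genes absent from the vector are
#'   treated as present (`TRUE`).
#' @return Logical scalar: is the reaction still catalysable? Rules with no
#'   gene association always evaluate `TRUE`.
#' @examples
#' eval_gpr(parse_gpr("G1 or G2"), c(G1 = FALSE))
#' @export
eval_gpr <- function(rule, gene_states = logical(0)) {
  stopifnot(inherits(rule, "gpr_rule"))
  if (is.null(rule$structure)) return(TRUE)
  gpr_eval_node(rule$structure, gene_states)
}

gpr_eval_node <- function(node, states) {
  if (is.character(node)) {
    if (node %in% names(states)) return(unname(states[[node]]))
    return(TRUE)
  }
  vals <- vapply(node$args, gpr_eval_node, logical(1), states = states)
  if (node$op == "and") all(vals) else any(vals)
}
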