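#' Gene-protein-reaction (GPR) rule parsing and evaluation
#'
#' GPR rules are boolean AND/OR expressions over gene ids that state which
#' gene products a reaction requires: `AND` joins subunits of a complex (all
#' required), `OR` joins isozymes (any suffices). Rules are stored as strings
#' (e.g. `"(g1 and g2) or g3"`) and parsed into nested lists with `op` in
#' `{"and","or"}` and `args`; a leaf is a plain gene id string.
#'
#' @param rule a GPR rule string, or NA/NULL/"" for "no rule".
#' @return parsed rule tree, or NULL when there is no rule.
#' @export
#' @examples
#' parse_gene_rule("(g1 and g2) or g3")
parse_gene_rule <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("malformed gene rule near '", st$toks[st$pos], "': ", rule)
  }
  tree
}

gpr_tokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1) args[[1]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("unexpected end of gene rule")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("unbalanced parentheses in gene rule")
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("malformed gene rule at '", tok, "'")
  }
  st$pos <- st$pos + 1L
  tok
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A gene leaf is active iff the gene is not deleted; `and` requires all
#' children active, `or` any. A reaction with no rule (NULL) is always active.
#'
#' @param rule parsed rule tree from [parse_gene_rule()] (or a rule string).
#' @param deleted character vector of deleted gene ids.
#' @return logical: is the reaction still catalyzed?
#' @export
evaluate_gene_rule <- function(rule, deleted = character()) {
  if (is.character(rule) && length(rule) == 1 && !is.list(rule) &&
      (grepl("\\s|\\(", rule))) {
    rule <- parse_gene_rule(rule)
  }
  if (is.null(rule)) return(TRUE)
  if (is.character(rule)) return(!(rule %in% deleted))
  vals <- vapply(rule$args, evaluate_gene_rule, logical(1), deleted = deleted)
  if (rule$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR rule
#' @param rule parsed rule tree or rule string.
#' @return character vector of gene ids (unique).
#' @export
rule_genes <- function(rule) {
  if (is.character(rule) && length(rule) == 1 && !is.list(rule)) {
    rule <- parse_gene_rule(rule)
  }
  if (is.null(rule)) return(character())
  if (is.character(rule)) return(rule)
  unique(unlist(lapply(rule$args, rule_genes)))
}

# Fold a rule over per-gene values with AND/OR combiners. Used both for
# expression-state propagation (AND = min, OR = max over an ordered scale)
# and for GIMME-style reaction-level expression (min/max over numeric values).
rule_fold <- function(rule, gene_values, and_fn = min, or_fn = max,
                      missing_value = NA) {
  if (is.null(rule)) return(missing_value)
  if (is.character(rule)) {
    v <- gene_values[[rule]]
    return(if (is.null(v) || is.na(v)) missing_value else v)
  }
  vals <- vapply(rule$args, rule_fold, numeric(1),
                 gene_values = gene_values, and_fn = and_fn, or_fn = or_fn,
                 missing_value = missing_value)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(missing_value)
  if (rule$op == "and") and_fn(vals) else or_fn(vals)
}
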