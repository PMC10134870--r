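# Gene-protein-reaction (GPR) boolean rules: "(g1 and g2) or g3".
# AND groups model enzyme complexes, OR groups isozymes.

#' Parse a GPR rule string
#'
#' Recursive-descent parser for boolean gene rules with `and`/`or`
#' (case-insensitive, `&`/`|` accepted) and parentheses. Returns a tree:
#' either a gene id (character leaf) or `list(op = "and"|"or", args = ...)`.
#'
#' @param rule GPR string; `NA` or `""` yields `NULL` (no rule).
#' @return parse tree, or `NULL` for an empty rule.
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule))) {
    return(NULL)
  }
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^\\s()]+", rule, perl = TRUE))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  is_op <- function(t, ops) !is.na(t) && tolower(t) %in% ops

  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (is_op(peek(), c("or", "|", "||"))) {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (is_op(peek(), c("and", "&", "&&"))) {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("malformed GPR rule: unexpected end in '", rule, "'")
    if (t == "(") {
      advance()
      node <- parse_or()
      if (!identical(peek(), ")")) stop("malformed GPR rule: missing ')' in '", rule, "'")
      advance()
      return(node)
    }
    if (t == ")" || is_op(t, c("and", "or", "&", "|"))) {
      stop("malformed GPR rule: unexpected '", t, "' in '", rule, "'")
    }
    advance()
  }
  out <- parse_or()
  if (pos <= length(toks)) stop("malformed GPR rule: trailing tokens in '", rule, "'")
  out
}

#' Genes referenced by a GPR rule
#' @param rule GPR string.
#' @return character vector of unique gene ids (empty for no rule).
#' @export
gpr_genes <- function(rule) {
  tree <- if (is.character(rule) || is.null(rule) || is.na(rule[1])) parse_gpr(rule) else rule
  leaves <- function(node) {
    if (is.null(node)) return(character(0))
    if (is.character(node)) return(node)
    unlist(lapply(node$args, leaves))
  }
  unique(leaves(tree))
}

#' Evaluate a GPR rule over per-gene values
#'
#' Applies `and_fn` (default `min`, conservative for complexes) over AND
#' groups and `or_fn` (default `max`, permissive for isozymes) over OR
#' groups. Genes absent from `values` are dropped from the evaluation;
#' a rule whose genes are all unmeasured evaluates to `NA`.
#'
#' @param rule GPR string or parse tree.
#' @param values named numeric vector of per-gene values.
#' @param and_fn,or_fn aggregation functions.
#' @return numeric scalar, or `NA` if no referenced gene is measured.
#' @export
eval_gpr <- function(rule, values, and_fn = min, or_fn = max) {
  tree <- if (is.character(rule) && length(rule) == 1L) parse_gpr(rule) else rule
  if (is.null(tree)) return(NA_real_)
  ev <- function(node) {
    if (is.character(node)) {
      return(if (node %in% names(values)) unname(values[[node]]) else NA_real_)
    }
    vals <- vapply(node$args, ev, numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$op == "and") and_fn(vals) else or_fn(vals)
  }
  ev(tree)
}
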