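# Gene-protein-reaction (GPR) rules. A GPR is a Boolean expression over gene
# identifiers with "and" (all subunits of a complex required) and "or"
# (isozymes). Rules are stored as strings and parsed into a tree of nested
# lists: a leaf is a character gene id, an internal node is
# list(op = "and"/"or", args = list(...)). "and" binds tighter than "or",
# matching the usual convention of constraint-based toolkits.

#' Parse a GPR rule string into an expression tree
#'
#' @param rule a string such as `"(g1 and g2) or g3"`; `""` or `NA` mean
#'   "no gene association" (spontaneous or orphan reaction).
#' @return a GPR tree (character leaf or `list(op=, args=)`), or `NULL` for an
#'   empty rule.
#' @export
gpr_parse <- function(rule) {
  if (is.null(rule) || length(rule) == 0L || is.na(rule) || !nzchar(trimws(rule)))
    return(NULL)
  toks <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_and()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_atom()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR rule: '", rule, "'")
    if (t == "(") {
      advance()
      e <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("unbalanced parentheses in GPR: '", rule, "'")
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("malformed GPR rule: '", rule, "'")
    advance()
  }
  out <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in GPR rule: '", rule, "'")
  out
}

#' Deparse a GPR tree back to its string form
#' @param expr a GPR tree as returned by [gpr_parse()].
#' @return a string (empty string for `NULL`).
#' @export
gpr_deparse <- function(expr) {
  if (is.null(expr)) return("")
  if (is.character(expr)) return(expr)
  parts <- vapply(expr$args, function(a) {
    s <- gpr_deparse(a)
    if (is.list(a)) paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", expr$op, " "))
}

#' Evaluate whether a reaction remains catalysable after gene deletions
#'
#' AND-nodes require all children, OR-nodes any child; a leaf is true iff the
#' gene is not deleted. An empty rule is always true (no gene requirement).
#'
#' @param expr GPR tree or rule string.
#' @param deleted character vector of deleted gene ids.
#' @return logical scalar.
#' @export
gpr_eval <- function(expr, deleted = character()) {
  if (is.character(expr) && length(expr) == 1L) expr <- gpr_parse(expr)
  if (is.null(expr)) return(TRUE)
  if (is.character(expr)) return(!(expr %in% deleted))
  vals <- vapply(expr$args, gpr_eval, logical(1), deleted = deleted)
  if (expr$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR tree
#' @param expr GPR tree or rule string.
#' @return character vector of unique gene ids (empty for no rule).
#' @export
gpr_genes <- function(expr) {
  if (is.character(expr) && length(expr) == 1L) expr <- gpr_parse(expr)
  if (is.null(expr)) return(character())
  if (is.character(expr)) return(expr)
  unique(unlist(lapply(expr$args, gpr_genes)))
}

#' Map gene expression onto a GPR rule
#'
#' AND-nodes aggregate by minimum (complex limited by its scarcest subunit),
#' OR-nodes by maximum (isozymes add capacity), recursively. A gene without
#' data inside an AND makes the node unscorable (`NA`); inside an OR the
#' remaining scored isozymes still count.
#'
#' @param expr GPR tree or rule string.
#' @param values named numeric vector of gene expression values.
#' @return numeric score, or `NA` if the rule cannot be scored.
#' @export
gpr_score <- function(expr, values) {
  if (is.character(expr) && length(expr) == 1L) expr <- gpr_parse(expr)
  if (is.null(expr)) return(NA_real_)
  if (is.character(expr)) {
    v <- values[expr]
    return(if (length(v) == 0L || is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(expr$args, gpr_score, numeric(1), values = values)
  if (expr$op == "and") {
    if (anyNA(vals)) NA_real_ else min(vals)
  } else {
    if (all(is.na(vals))) NA_real_ else max(vals, na.rm = TRUE)
  }
}
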