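# Chemical formula handling. Formulas are stored as plain strings
# ("C6H12O6") and parsed on demand into named integer vectors. Pseudo-element
# symbols are permitted: "R" marks a conserved alkyl moiety carried unchanged
# through acyl chemistry, and single-letter placeholders (X, Y, ...) are used
# by lumped cofactor pairs in toy networks. Pseudo-elements have zero mass.

.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007, P = 30.974,
                  S = 32.06, Fe = 55.845, Mg = 24.305, K = 39.098, Na = 22.99,
                  Ca = 40.078, Zn = 65.38, Cl = 35.45)

#' Parse a chemical formula string
#'
#' @param formula a string such as `"C6H12O6"`; element symbols are one upper
#'   case letter optionally followed by a lower case letter, each with an
#'   optional integer count (default 1). `NA` or `""` mean "no formula".
#' @return named integer vector of element counts, or `NULL` for no formula.
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula takes a single string")
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("malformed formula: '", formula, "'")
  sym <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]", toks), sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(cnt, sym, sum)
  storage.mode(out) <- "integer"
  out[order(names(out))]
}

#' Molar mass of a formula (g/mol)
#'
#' Pseudo-elements (anything not in the internal atomic-mass table) weigh
#' zero, so lumped cofactors do not contribute to mass-based yields.
#'
#' @param formula formula string.
#' @return molar mass in g/mol (0 for empty formula).
#' @export
formula_mass <- function(formula) {
  el <- parse_formula(formula)
  if (is.null(el)) return(0)
  w <- .ATOMIC_MASS[names(el)]
  w[is.na(w)] <- 0
  sum(w * el)
}

# element counts of a formula as contributions to a running total
.add_elements <- function(total, formula, coef) {
  el <- parse_formula(formula)
  if (is.null(el)) return(total)
  for (s in names(el)) {
    total[s] <- (if (s %in% names(total)) total[[s]] else 0) + coef * el[[s]]
  }
  total
}
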