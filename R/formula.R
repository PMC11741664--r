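#' Parse a chemical formula string into element counts
#'
#' Formulas use Hill-style notation: an element symbol (one uppercase letter
#' optionally followed by one lowercase letter) followed by an optional integer
#' count. Residue placeholders such as `R` (acyl-carrier moiety) are treated as
#' ordinary elements, which keeps balance arithmetic exact for toy networks.
#'
#' @param formula character scalar, e.g. `"C2H4O2"`. `NA` or `""` yield `NULL`.
#' @return named integer vector of element counts, or `NULL` when the formula
#'   is missing.
#' @examples
#' parse_formula("C4H6O2")
#' @export
parse_formula <- function(formula) {
  if (length(formula) != 1L) stop("parse_formula() expects a single string")
  if (is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(formula)) {
    stop("malformed formula: '", formula, "'")
  }
  el <- sub("[0-9]*$", "", tokens)
  n <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                         sub("^[A-Za-z]+", "", tokens), "1"))
  counts <- tapply(n, el, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Render element counts back into a formula string
#'
#' @param counts named integer vector as returned by [parse_formula()].
#' @return character scalar; `""` for `NULL` input.
#' @export
deparse_formula <- function(counts) {
  if (is.null(counts) || length(counts) == 0) return("")
  counts <- counts[counts != 0]
  ord <- order(names(counts))
  paste0(names(counts)[ord],
         ifelse(counts[ord] == 1L, "", counts[ord]), collapse = "")
}

#' Count atoms of one element in a formula
#'
#' @param formula formula string.
#' @param element element symbol, e.g. `"C"` or `"N"`.
#' @return integer count (0 when absent or formula missing).
#' @export
count_element <- function(formula, element) {
  counts <- parse_formula(formula)
  if (is.null(counts) || !element %in% names(counts)) return(0L)
  unname(counts[[element]])
}
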