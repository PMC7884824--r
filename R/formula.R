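#' Parse a molecular formula string
#'
#' Parses strings like `"C4H6O5"` or `"H2O"` into a named integer vector of
#' element counts. Repeated element symbols are summed, so `"CH3COOH"` and
#' `"C2H4O2"` parse to the same counts.
#'
#' @param text Molecular formula string. Element symbols are one capital
#'   letter optionally followed by one lowercase letter, each optionally
#'   followed by a positive integer count (absent count means 1).
#' @return Named integer vector, element symbol -> count, in Hill order
#'   (C, then H, then other elements alphabetically; all alphabetical when
#'   no carbon is present).
#' @examples
#' parse_formula("C4H6O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("cannot parse formula: ", sQuote(text))
  known <- names(element_masses())
  counts <- integer(0)
  for (tok in toks) {
    sym <- sub("[0-9]*$", "", tok)
    num <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(num)) as.integer(num) else 1L
    if (!sym %in% known)
      stop("unknown element symbol: ", sQuote(sym))
    if (n <= 0L)
      stop("element count must be positive: ", sQuote(tok))
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  hill_order(counts)
}

# canonical Hill ordering of an element-count vector
hill_order <- function(counts) {
  syms <- names(counts)
  if ("C" %in% syms) {
    rest <- sort(setdiff(syms, c("C", "H")))
    ord <- c("C", intersect("H", syms), rest)
  } else {
    ord <- sort(syms)
  }
  counts[ord]
}

#' Serialize element counts to a Hill-order formula string
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(x))` always
#' equals `hill`-ordered `x`.
#'
#' @param counts Named integer vector of element counts.
#' @return Formula string such as `"C4H6O5"`.
#' @export
format_formula <- function(counts) {
  counts <- hill_order(counts[counts > 0])
  paste0(names(counts), ifelse(counts == 1L, "", counts), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param f Named integer vector of element counts (as from
#'   [parse_formula()]) or a formula string.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")     # 18.0106
#' monoisotopic_mass("C4H6O5")  # malic acid, 134.0215
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  if (length(f) == 0L || all(f == 0L)) stop("empty formula")
  masses <- element_masses()
  missing <- setdiff(names(f), names(masses))
  if (length(missing))
    stop("element(s) missing from mass table: ", paste(missing, collapse = ", "))
  sum(masses[names(f)] * as.numeric(f))
}
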