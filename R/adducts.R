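#' Default electrospray adduct rules
#'
#' The singly charged adduct species used for MS1 annotation. Mass shifts
#' follow the charged-species convention: a protonated ion adds a proton
#' (H minus an electron, 1.0072765 Da), a deprotonated ion subtracts one,
#' a radical cation `[M]+` subtracts one electron mass, and anion attachment
#' (formate, acetate) adds the neutral group plus one electron. Both the
#' formate and acetate attachment rules ship in the negative-mode set;
#' methods sections and peak tables in this field name one or the other
#' interchangeably.
#'
#' @return data.frame with columns `name`, `polarity` (`"pos"`/`"neg"`),
#'   `shift` (Da, signed), `charge` (integer, always 1 here).
#' @examples
#' default_adducts()
#' @export
default_adducts <- function() {
  e <- ELECTRON_MASS
  formate <- monoisotopic_mass(c(C = 1L, H = 1L, O = 2L))
  acetate <- monoisotopic_mass(c(C = 2L, H = 3L, O = 2L))
  na <- element_masses()[["Na"]]
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M]+", "[M-H]-", "[M+HCOO]-", "[M+CH3COO]-"),
    polarity = c("pos", "pos", "pos", "neg", "neg", "neg"),
    shift = c(PROTON_MASS, na - e, -e, -PROTON_MASS, formate + e, acetate + e),
    charge = 1L,
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of an adduct ion
#'
#' `(monoisotopic mass + shift) / charge` for the named rule.
#'
#' @param f Molecular formula (string or named count vector).
#' @param adduct Adduct name, e.g. `"[M-H]-"`, or a single-row rule
#'   data.frame.
#' @param rules Adduct rule set to look the name up in.
#' @return Theoretical m/z (Th).
#' @examples
#' adduct_mz("C4H6O5", "[M-H]-")   # 133.0142
#' adduct_mz("C15H10O4", "[M+H]+") # 255.0652
#' @export
adduct_mz <- function(f, adduct, rules = default_adducts()) {
  if (is.character(adduct)) {
    i <- match(adduct, rules$name)
    if (is.na(i)) stop("unknown adduct: ", sQuote(adduct))
    rule <- rules[i, ]
  } else {
    rule <- adduct
  }
  (monoisotopic_mass(f) + rule$shift) / rule$charge
}

#' Signed relative mass error in parts per million
#'
#' `(measured - theoretical) / theoretical * 1e6`. Positive when the
#' measurement is heavier than theory.
#'
#' @param measured Measured m/z (Th).
#' @param theoretical Theoretical m/z (Th), must be positive.
#' @return Signed ppm error.
#' @examples
#' ppm_error(100.001, 100) # 10
#' @export
ppm_error <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (measured - theoretical) / theoretical * 1e6
}
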