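#' Monoisotopic element masses
#'
#' Returns the table of monoisotopic atomic masses (Da) used throughout the
#' mass-annotation stage. Masses are those of the most abundant isotope
#' (NIST/CODATA); carbon is exactly 12 by definition.
#'
#' @return Named numeric vector, element symbol -> monoisotopic mass in Da.
#' @examples
#' element_masses()[["C"]] # 12 exactly
#' @export
element_masses <- function() {
  c(
    C  = 12.0,
    H  = 1.00782503207,
    N  = 14.0030740048,
    O  = 15.9949146196,
    S  = 31.97207100,
    P  = 30.97376163,
    Na = 22.9897692809,
    K  = 38.96370668,
    Cl = 34.96885268,
    F  = 18.99840322,
    Br = 78.9183371,
    I  = 126.904473,
    Se = 79.9165213
  )
}

# electron rest mass in Da; a protonated ion is M + H - e
ELECTRON_MASS <- 0.000548579909
PROTON_MASS <- 1.00782503207 - 0.000548579909
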