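#' Named neutral-loss table
#'
#' Small-molecule neutral losses commonly seen in MS2 spectra of plant
#' secondary metabolites, plus all their multiset combinations up to
#' `max_combo` units (e.g. `"2CO"`, `"H2O+CO"`). Loss masses are computed
#' from the monoisotopic element table.
#'
#' @param max_combo Maximum number of units combined in a composite loss.
#' @param base Named character vector, loss name -> molecular formula.
#' @return data.frame with columns `name` and `mass` (Da), single losses
#'   first, sorted by mass within each combination order.
#' @export
default_losses <- function(max_combo = 3,
                           base = c(H2O = "H2O", CO = "CO", CO2 = "CO2",
                                    NH3 = "NH3")) {
  stopifnot(max_combo >= 1)
  masses <- vapply(base, monoisotopic_mass, numeric(1))
  nb <- length(base)
  out <- list()
  # enumerate count vectors over the base losses with total 1..max_combo
  counts <- expand.grid(rep(list(0:max_combo), nb))
  counts <- counts[rowSums(counts) >= 1 & rowSums(counts) <= max_combo, , drop = FALSE]
  nm <- apply(counts, 1, function(k) {
    used <- which(k > 0)
    paste0(ifelse(k[used] > 1, k[used], ""), names(base)[used], collapse = "+")
  })
  df <- data.frame(name = nm, mass = as.numeric(as.matrix(counts) %*% masses),
                   order = rowSums(counts), stringsAsFactors = FALSE)
  df <- df[order(df$order, df$mass), c("name", "mass")]
  rownames(df) <- NULL
  df
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Assign neutral losses to MS2 fragments
#'
#' For each fragment, computes the nominal (integer) and exact loss from the
#' precursor and tries to name it from a table of small-molecule losses and
#' their combinations. Matching is two-pass: first exact mass within `tol`
#' Da; if nothing matches — typical when m/z values are quoted at nominal
#' precision, as in published fragmentation schemes — a fallback match on
#' the nominal integer mass is attempted and flagged as such. Unmatched
#' fragments are kept and flagged, never dropped.
#'
#' @param precursor Precursor m/z (Th).
#' @param fragments Numeric vector of fragment m/z, each `<= precursor`.
#' @param losses Loss table, see [default_losses()].
#' @param tol Exact-loss match tolerance in Da.
#' @return data.frame with columns `precursor_mz`, `fragment_mz`,
#'   `nominal_loss` (integer Da, rounded half away from zero),
#'   `exact_loss` (Da), `loss_name` (NA when unmatched), `match_type`
#'   (`"exact"`, `"nominal"`, or `"none"`). Row order follows `fragments`.
#' @examples
#' annotate_neutral_losses(255, c(227, 199)) # CO, then 2CO
#' @export
annotate_neutral_losses <- function(precursor, fragments,
                                    losses = default_losses(), tol = 0.01) {
  stopifnot(length(precursor) == 1L, precursor > 0)
  if (any(fragments > precursor))
    stop("fragment m/z exceeds precursor m/z")
  rows <- lapply(fragments, function(fr) {
    exact <- precursor - fr
    nominal <- round_half_up(exact)
    d <- abs(losses$mass - exact)
    name <- NA_character_
    type <- "none"
    if (any(d <= tol)) {
      name <- losses$name[which.min(d)]
      type <- "exact"
    } else {
      nom_hit <- which(round_half_up(losses$mass) == nominal)
      if (length(nom_hit)) {
        name <- losses$name[nom_hit[which.min(d[nom_hit])]]
        type <- "nominal"
      }
    }
    data.frame(precursor_mz = precursor, fragment_mz = fr,
               nominal_loss = as.integer(nominal), exact_loss = exact,
               loss_name = name, match_type = type, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
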