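#' Annotate MS1 peaks against a compound library
#'
#' Matches every peak against every (compound, adduct) pair of matching
#' polarity and keeps the pairs whose theoretical m/z lies within `tol` ppm
#' of the measured m/z. All candidates within tolerance are reported — no
#' forced uniqueness — because disambiguation is done downstream (MS2,
#' literature). Per peak, candidates are sorted by absolute ppm error
#' ascending.
#'
#' @param peaks data.frame with columns `rt_min`, `mz`, `polarity`
#'   (`"pos"`/`"neg"`) and optionally `intensity`.
#' @param library data.frame with columns `id`, `name`, `formula`.
#' @param rules Adduct rule set, see [default_adducts()].
#' @param tol ppm tolerance; the default 10 ppm is the usual accuracy
#'   threshold for this instrument class, 5 ppm is a common stricter choice.
#' @param scan_range Optional length-2 numeric; peaks with m/z outside the
#'   instrument scan range (e.g. `c(50, 1500)`) are dropped with a warning.
#'   `NULL` (default) disables the check.
#' @return data.frame with one row per (peak, compound, adduct) hit:
#'   `peak` (row index into `peaks`), `rt_min`, `mz`, `polarity`,
#'   `compound_id`, `compound_name`, `adduct`, `theoretical_mz`,
#'   `ppm_error`. Every row satisfies `abs(ppm_error) <= tol`.
#' @examples
#' lib <- data.frame(id = "c1", name = "malic acid", formula = "C4H6O5")
#' pk <- data.frame(rt_min = 1, mz = 133.0142, polarity = "neg")
#' annotate_peaks(pk, lib)
#' @export
annotate_peaks <- function(peaks, library, rules = default_adducts(),
                           tol = 10, scan_range = NULL) {
  stopifnot(tol > 0)
  if (nrow(rules) == 0L) stop("empty adduct rule set")
  empty <- data.frame(
    peak = integer(0), rt_min = numeric(0), mz = numeric(0),
    polarity = character(0), compound_id = character(0),
    compound_name = character(0), adduct = character(0),
    theoretical_mz = numeric(0), ppm_error = numeric(0),
    stringsAsFactors = FALSE
  )
  if (nrow(library) == 0L) {
    warning("empty compound library; no annotations")
    return(empty)
  }
  if (any(peaks$mz <= 0)) stop("peak m/z must be positive")
  peaks$.row <- seq_len(nrow(peaks))
  if (!is.null(scan_range)) {
    out_of_range <- peaks$mz < scan_range[1] | peaks$mz > scan_range[2]
    if (any(out_of_range)) {
      warning(sum(out_of_range), " peak(s) outside scan range dropped")
      peaks <- peaks[!out_of_range, , drop = FALSE]
    }
  }
  if (nrow(peaks) == 0L) return(empty)

  # theoretical m/z for every (compound, rule) pair, computed once
  mono <- vapply(library$formula, monoisotopic_mass, numeric(1), USE.NAMES = FALSE)
  grid <- expand.grid(ci = seq_len(nrow(library)), ri = seq_len(nrow(rules)))
  grid$theo <- (mono[grid$ci] + rules$shift[grid$ri]) / rules$charge[grid$ri]
  grid$pol <- rules$polarity[grid$ri]

  res <- lapply(seq_len(nrow(peaks)), function(i) {
    cand <- grid[grid$pol == peaks$polarity[i], , drop = FALSE]
    err <- ppm_error(peaks$mz[i], cand$theo)
    keep <- abs(err) <= tol
    if (!any(keep)) return(NULL)
    cand <- cand[keep, , drop = FALSE]
    err <- err[keep]
    o <- order(abs(err))
    data.frame(
      peak = peaks$.row[i], rt_min = peaks$rt_min[i], mz = peaks$mz[i],
      polarity = peaks$polarity[i],
      compound_id = as.character(library$id[cand$ci][o]),
      compound_name = as.character(library$name[cand$ci][o]),
      adduct = rules$name[cand$ri][o],
      theoretical_mz = cand$theo[o], ppm_error = err[o],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(list(empty), res))
  rownames(out) <- NULL
  out
}
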