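#' Construct a gene-set collection
#'
#' @param sets Named list of character vectors of gene symbols (uppercased
#'   internally; every set must be non-empty; names unique).
#' @param descriptions Optional character vector of set descriptions.
#' @param background Optional background gene universe; defaults to the
#'   union of all set members.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, background = NULL) {
  if (!length(sets) || is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must be a non-empty uniquely named list")
  sets <- lapply(sets, function(s) unique(toupper(s)))
  if (any(vapply(sets, length, 1L) == 0L)) stop("every gene set must be non-empty")
  if (is.null(background)) background <- unique(unlist(sets, use.names = FALSE))
  background <- unique(toupper(background))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  structure(list(sets = sets, descriptions = descriptions,
                 background = background), class = "gene_set_collection")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn without
#' replacement from a universe of `N` containing `K` annotated ones.
#' Computed in log space via `lchoose` for numerical stability.
#'
#' @param k Observed overlap.
#' @param K Gene-set size (within the background).
#' @param n Query size.
#' @param N Background universe size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeom_upper_tail(2, 5, 2, 10) # 10/45
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || any(c(k, K, n, N) < 0))
    stop("inconsistent hypergeometric counts")
  if (k == 0) return(1)
  i <- k:min(K, n)
  terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(terms)
  min(1, exp(m + log(sum(exp(terms - m)))))
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in the query via the
#' hypergeometric upper tail. Query genes outside the background are
#' dropped with a warning. The significance flag applies the strict raw
#' p < `alpha` rule; a Benjamini-Hochberg adjusted column is emitted
#' alongside for good practice but does not drive the flag.
#'
#' @param query Character vector of gene symbols.
#' @param coll A [gene_set_collection()].
#' @param alpha Raw-p significance cutoff (strict `<`).
#' @param ease If `TRUE`, uses the EASE-modified score (overlap decremented
#'   by one, conservative); off by default.
#' @return data.frame, one row per set, sorted by p ascending: `name`,
#'   `k`, `K`, `n`, `N`, `p`, `p_BH`, `significant`.
#' @export
run_enrichment <- function(query, coll, alpha = 0.05, ease = FALSE) {
  stopifnot(inherits(coll, "gene_set_collection"))
  query <- unique(toupper(query))
  if (!length(query)) stop("empty query gene set")
  outside <- setdiff(query, coll$background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside background dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("no query genes in background")
  N <- length(coll$background)
  n <- length(query)
  rows <- lapply(names(coll$sets), function(nm) {
    set <- intersect(coll$sets[[nm]], coll$background)
    K <- length(set)
    k <- length(intersect(query, set))
    keff <- if (ease) max(k - 1L, 0L) else k
    data.frame(name = nm, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(keff, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_BH <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p, res$name), ]
  rownames(res) <- NULL
  res
}
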