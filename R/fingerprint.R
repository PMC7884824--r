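#' Construct a binary fingerprint
#'
#' A fingerprint is the set of set-bit indices of a binary structural
#' descriptor. Generation of fingerprints from structures is out of scope;
#' the package consumes precomputed bit sets.
#'
#' @param id Compound or drug identifier.
#' @param bits Integer vector of set-bit indices (non-negative; duplicates
#'   collapsed).
#' @param length Optional declared fingerprint length; all indices must be
#'   smaller.
#' @return Object of class `fingerprint`.
#' @export
fingerprint <- function(id, bits, length = NULL) {
  bits <- sort(unique(as.integer(bits)))
  if (any(bits < 0)) stop("bit indices must be non-negative")
  if (!is.null(length) && any(bits >= length))
    stop("bit index exceeds declared fingerprint length")
  structure(list(id = as.character(id), bits = bits, length = length),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("fingerprint", x$id, "-", length(x$bits), "set bits",
      if (!is.null(x$length)) paste0("/ ", x$length), "\n")
  invisible(x)
}

#' Construct a drug record
#'
#' @param drug_id Drug identifier.
#' @param fp [fingerprint()] of the drug.
#' @param targets Character vector of target gene symbols (uppercased,
#'   deduplicated; must be non-empty).
#' @return Object of class `drug_record`.
#' @export
drug_record <- function(drug_id, fp, targets) {
  targets <- unique(toupper(targets))
  targets <- targets[nzchar(targets)]
  if (!length(targets)) stop("drug record needs at least one target gene")
  structure(list(drug_id = as.character(drug_id), fingerprint = fp,
                 targets = targets), class = "drug_record")
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|`. Two empty fingerprints score 0 with a
#' warning: an empty bit set carries no structural evidence, so it should
#' not count as a perfect match.
#'
#' @param a,b Fingerprints (or plain integer vectors of set bits).
#' @return Similarity in \[0, 1\].
#' @examples
#' tanimoto(c(1, 2, 3), c(2, 3, 4)) # 0.5
#' @export
tanimoto <- function(a, b) {
  ba <- if (inherits(a, "fingerprint")) a$bits else unique(as.integer(a))
  bb <- if (inherits(b, "fingerprint")) b$bits else unique(as.integer(b))
  u <- length(union(ba, bb))
  if (u == 0L) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(ba, bb)) / u
}

#' Transfer drug targets to a query compound by similarity
#'
#' Computes the Tanimoto similarity between the query fingerprint and every
#' drug in the library; the targets of all drugs at or above `threshold`
#' (inclusive) are transferred to the query. One row is produced per
#' (query, gene), aggregating the supporting drugs and the maximum
#' similarity among them.
#'
#' @param query A [fingerprint()].
#' @param drugs List of [drug_record()]s.
#' @param threshold Similarity cutoff in \[0, 1\]; the conventional
#'   moderate-high similarity cutoff 0.8 is the default.
#' @param union_targets If `FALSE`, only the single best-scoring drug
#'   contributes targets (ties broken by drug order). Default `TRUE`:
#'   targets of all qualifying drugs are unioned.
#' @return data.frame with columns `compound_id`, `gene`,
#'   `max_similarity`, `supporting_drugs` (semicolon-joined), sorted by
#'   gene.
#' @export
predict_targets <- function(query, drugs, threshold = 0.8,
                            union_targets = TRUE) {
  stopifnot(threshold >= 0, threshold <= 1)
  empty <- data.frame(compound_id = character(0), gene = character(0),
                      max_similarity = numeric(0),
                      supporting_drugs = character(0), stringsAsFactors = FALSE)
  if (!length(drugs)) {
    warning("empty drug library; no predictions")
    return(empty)
  }
  sims <- vapply(drugs, function(d) tanimoto(query, d$fingerprint), numeric(1))
  hit <- which(sims >= threshold)
  if (!length(hit)) return(empty)
  if (!union_targets) hit <- hit[which.max(sims[hit])]
  per_gene <- new.env(parent = emptyenv())
  for (i in hit) {
    d <- drugs[[i]]
    for (g in d$targets) {
      prev <- if (!is.null(per_gene[[g]])) per_gene[[g]] else
        list(sim = -Inf, drugs = character(0))
      per_gene[[g]] <- list(sim = max(prev$sim, sims[i]),
                            drugs = c(prev$drugs, d$drug_id))
    }
  }
  genes <- sort(ls(per_gene))
  data.frame(
    compound_id = query$id,
    gene = genes,
    max_similarity = vapply(genes, function(g) per_gene[[g]]$sim, numeric(1)),
    supporting_drugs = vapply(genes, function(g)
      paste(sort(unique(per_gene[[g]]$drugs)), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Union per-compound target predictions into a putative target set
#'
#' Deduplicated union across compounds, keeping per-gene provenance (which
#' compounds predict each gene).
#'
#' @param preds data.frame of predictions (rows from [predict_targets()]
#'   over several compounds, rbind-ed).
#' @return data.frame with columns `gene`, `n_compounds`, `compounds`
#'   (semicolon-joined), sorted by gene.
#' @export
aggregate_targets <- function(preds) {
  if (!nrow(preds))
    return(data.frame(gene = character(0), n_compounds = integer(0),
                      compounds = character(0), stringsAsFactors = FALSE))
  sp <- split(preds$compound_id, preds$gene)
  genes <- sort(names(sp))
  data.frame(
    gene = genes,
    n_compounds = vapply(sp[genes], function(x) length(unique(x)), integer(1)),
    compounds = vapply(sp[genes], function(x)
      paste(sort(unique(x)), collapse = ";"), character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
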