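# Readers and writers for the plain-text interchange formats the pipeline
# uses: peak CSV, compound/fingerprint/drug/edge TSV, GMT, Ct CSV, SIF.

#' Read a peak table
#'
#' CSV with header columns `rt_min`, `mz`, `polarity` (`pos`/`neg`) and
#' optionally `intensity`.
#'
#' @param path File path.
#' @return data.frame of peaks.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rt_min", "mz", "polarity")
  if (!all(need %in% names(df)))
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  if (!all(df$polarity %in% c("pos", "neg")))
    stop("polarity must be 'pos' or 'neg'")
  df
}

#' Read a compound library
#'
#' TSV with columns `id`, `name`, `formula`.
#'
#' @param path File path.
#' @return data.frame of compounds.
#' @export
read_compound_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "name", "formula")
  if (!all(need %in% names(df)))
    stop("compound library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$id)) stop("compound ids must be unique")
  df
}

#' Write peak annotations
#'
#' TSV with peak fields, compound id, adduct, theoretical m/z and ppm
#' error; m/z columns fixed to 6 decimal places.
#'
#' @param ann Annotation data.frame from [annotate_peaks()].
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  out <- ann
  for (col in c("mz", "theoretical_mz"))
    out[[col]] <- sprintf("%.6f", out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read fingerprints
#'
#' TSV mapping `id` to a comma-separated list of set-bit indices, with an
#' optional `length` column declaring the fingerprint length.
#'
#' @param path File path.
#' @return List of fingerprints (see [fingerprint()]).
#' @export
read_fingerprints <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("id", "bits") %in% names(df)))
    stop("fingerprint file must have columns id, bits")
  len <- if ("length" %in% names(df)) as.integer(df$length) else rep(NA_integer_, nrow(df))
  fps <- lapply(seq_len(nrow(df)), function(i) {
    bits <- if (nzchar(df$bits[i])) as.integer(strsplit(df$bits[i], ",")[[1]]) else integer(0)
    fingerprint(df$id[i], bits, length = if (is.na(len[i])) NULL else len[i])
  })
  names(fps) <- df$id
  fps
}

#' Read a drug library
#'
#' TSV with columns `drug_id`, `bits` (comma-separated set-bit indices) and
#' `targets` (semicolon-separated gene symbols).
#'
#' @param path File path.
#' @return List of drug records (see [drug_record()]).
#' @export
read_drug_library <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("drug_id", "bits", "targets")
  if (!all(need %in% names(df)))
    stop("drug library must have columns: ", paste(need, collapse = ", "))
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    bits <- if (nzchar(df$bits[i])) as.integer(strsplit(df$bits[i], ",")[[1]]) else integer(0)
    drug_record(df$drug_id[i], fingerprint(df$drug_id[i], bits),
                strsplit(df$targets[i], ";")[[1]])
  })
  names(drugs) <- df$drug_id
  drugs
}

#' Write target predictions
#'
#' TSV with columns `compound_id`, `gene`, `max_similarity`,
#' `supporting_drugs`.
#'
#' @param preds Prediction data.frame from [predict_targets()].
#' @param path Output path.
#' @export
write_predictions <- function(preds, path) {
  utils::write.table(preds, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a confidence-scored edge list
#'
#' TSV with columns `node_a`, `node_b`, `combined_score`. Scores on the
#' 0-1000 integer scale (STRING convention) are autodetected and divided by
#' 1000; scores already in \[0, 1\] are kept as-is.
#'
#' @param path File path.
#' @return data.frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_a", "node_b", "combined_score")
  if (!all(need %in% names(df)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  score <- as.numeric(df$combined_score)
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0 | score > 1)) stop("scores outside both 0-1 and 0-1000 scales")
  data.frame(node_a = df$node_a, node_b = df$node_b, confidence = score,
             stringsAsFactors = FALSE)
}

#' Export a network in SIF format
#'
#' One `node_a <relation> node_b` line per edge, suitable for desktop
#' network viewers.
#'
#' @param net A `pharm_network`.
#' @param path Output path.
#' @param relation Interaction type label.
#' @export
write_sif <- function(net, path, relation = "pp") {
  el <- igraph::as_edgelist(net$graph)
  lines <- if (nrow(el)) paste(el[, 1], relation, el[, 2]) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write the node-attribute table
#'
#' TSV with role, the three centralities, and hub/major-hub flags per node.
#'
#' @param net A `pharm_network`.
#' @param sel A `hub_selection` from [classify_candidates()], or NULL.
#' @param path Output path.
#' @export
write_node_attributes <- function(net, sel = NULL, path) {
  cen <- centralities(net)
  cen$role <- net$roles[cen$node]
  if (!is.null(sel)) {
    cen$hub <- cen$node %in% sel$hubs
    cen$major_hub <- cen$node %in% sel$major_hubs
    cen$candidate_target <- cen$node %in% sel$candidate_targets
  }
  utils::write.table(cen, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-delimited lines: set name, description, then member genes. Gene
#' symbols are uppercased.
#'
#' @param path File path.
#' @param background Optional background gene universe; defaults to the
#'   union of all set members.
#' @return A `gene_set_collection`: list with `sets` (named list of gene
#'   vectors), `descriptions`, `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad)) stop("GMT lines must have at least 3 fields")
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) stop("gene-set names must be unique")
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- nm
  gene_set_collection(sets,
                      descriptions = vapply(parts, `[[`, "", 2L),
                      background = background)
}

#' Write enrichment results
#'
#' TSV with columns name, k, K, n, N, p, p_BH, significant.
#'
#' @param res Enrichment data.frame from [run_enrichment()].
#' @param path Output path.
#' @export
write_enrichment <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' CSV with columns `sample`, `group`, `gene`, `ct`, `replicate`.
#'
#' @param path File path.
#' @return data.frame of Ct measurements.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "group", "gene", "ct", "replicate")
  if (!all(need %in% names(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$ct) | df$ct <= 0)) stop("Ct values must be positive and finite")
  df
}
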