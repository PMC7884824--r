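#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification. Technical replicates are averaged on the
#' Ct scale; per sample, dCt = Ct(gene) - Ct(reference gene); ddCt
#' subtracts the mean dCt of the control-group samples for the same gene;
#' fold change = 2^-ddCt. The reference gene itself is not reported.
#'
#' @param ct data.frame with columns `sample`, `group`, `gene`, `ct`,
#'   `replicate` (see [read_ct_table()]).
#' @param ref_gene Reference (housekeeping) gene symbol, measured in every
#'   sample.
#' @param control_group Group label whose mean dCt defines the baseline.
#' @return data.frame with one row per (sample, target gene): `sample`,
#'   `group`, `gene`, `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("s1", "s2"), each = 2),
#'   group = rep(c("control", "treated"), each = 2),
#'   gene = rep(c("ACTB", "AKT1"), 2),
#'   ct = c(18, 24, 18, 23), replicate = 1
#' )
#' relative_expression(ct, "ACTB", "control") # treated AKT1 fold = 2
#' @export
relative_expression <- function(ct, ref_gene = "ACTB",
                                control_group = "control") {
  need <- c("sample", "group", "gene", "ct")
  stopifnot(all(need %in% names(ct)))
  if (!control_group %in% ct$group)
    stop("unknown control group: ", sQuote(control_group))
  # replicate average on the Ct scale, one Ct per (sample, gene)
  agg <- stats::aggregate(ct ~ sample + group + gene, data = ct, FUN = mean)
  ref <- agg[agg$gene == ref_gene, c("sample", "ct")]
  if (!all(unique(agg$sample) %in% ref$sample))
    stop("reference gene ", sQuote(ref_gene), " missing for some sample(s)")
  names(ref)[2] <- "ref_ct"
  tgt <- agg[agg$gene != ref_gene, , drop = FALSE]
  tgt <- merge(tgt, ref, by = "sample")
  tgt$delta_ct <- tgt$ct - tgt$ref_ct
  base <- stats::aggregate(delta_ct ~ gene,
                           data = tgt[tgt$group == control_group, ], FUN = mean)
  names(base)[2] <- "base_dct"
  tgt <- merge(tgt, base, by = "gene")
  tgt$delta_delta_ct <- tgt$delta_ct - tgt$base_dct
  tgt$fold_change <- 2^(-tgt$delta_delta_ct)
  out <- tgt[order(tgt$gene, tgt$sample),
             c("sample", "group", "gene", "delta_ct", "delta_delta_ct",
               "fold_change")]
  rownames(out) <- NULL
  out
}

#' Group-level fold-change summary
#'
#' Mean and standard deviation of per-sample fold changes by (group, gene).
#'
#' @param rel Output of [relative_expression()].
#' @return data.frame with columns `group`, `gene`, `n`, `mean_fold`,
#'   `sd_fold`.
#' @export
summarize_folds <- function(rel) {
  sp <- split(rel$fold_change, list(rel$group, rel$gene), drop = TRUE)
  key <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(group = key[, 1], gene = key[, 2],
                    n = vapply(sp, length, 1L),
                    mean_fold = vapply(sp, mean, 1),
                    sd_fold = vapply(sp, stats::sd, 1),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$gene, out$group), ]
}
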