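# Orchestration: configuration, fixture writing, the end-to-end run and
# its machine-readable report.

# FNV-1a over the serialized config; stable across sessions, no external
# digest dependency
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483648 - 2147483648 * (h >= 2147483648)),
                 ch)
    h <- (as.numeric(h) %% 4294967296) * 16777619 %% 4294967296
    h <- h %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

log_msg <- function(level, ..., min_level = getOption("netpharm.log_level", "INFO")) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[[level]] >= levels[[min_level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Pipeline run configuration
#'
#' Paths for every input, the stage parameters, and stage toggles. Any
#' stage whose toggle is off (or whose inputs are not supplied) is
#' skipped.
#'
#' @param peaks,compound_library Paths for the annotation stage.
#' @param fingerprints,drug_library Paths for the target-prediction stage.
#' @param edges,disease_genes Paths for the network stage (edge TSV and a
#'   plain-text gene list, one symbol per line).
#' @param gene_sets GMT path for the enrichment stage.
#' @param ct_table Optional Ct CSV for the qPCR stage.
#' @param out_dir Output directory; every intermediate artifact is written
#'   there (auditability: any stage can be re-run and diffed).
#' @param tol ppm tolerance for annotation.
#' @param similarity_threshold Tanimoto cutoff for target transfer.
#' @param min_conf Minimum edge confidence.
#' @param alpha Enrichment significance cutoff (raw p, strict `<`).
#' @param ref_gene,control_group qPCR reference gene and baseline group.
#' @param seed Seed recorded in the report (the pipeline itself is
#'   deterministic given fixed inputs).
#' @param stages Character vector of stages to run, in order, among
#'   `"annotate"`, `"predict"`, `"network"`, `"enrich"`, `"qpcr"`.
#' @return List of class `run_config`.
#' @export
run_config <- function(peaks = NULL, compound_library = NULL,
                       fingerprints = NULL, drug_library = NULL,
                       edges = NULL, disease_genes = NULL,
                       gene_sets = NULL, ct_table = NULL,
                       out_dir = "netpharm_out",
                       tol = 10, similarity_threshold = 0.8,
                       min_conf = 0.4, alpha = 0.05,
                       ref_gene = "ACTB", control_group = "control",
                       seed = 1,
                       stages = c("annotate", "predict", "network",
                                  "enrich", "qpcr")) {
  stopifnot(tol > 0, similarity_threshold >= 0, similarity_threshold <= 1,
            min_conf >= 0, min_conf <= 1, alpha > 0, alpha < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Write every synthetic fixture the pipeline consumes
#'
#' Generates all five fixtures from one [sim_config()] and writes them, in
#' the exact formats the pipeline reads, plus one truth JSON per fixture.
#' The network and enrichment fixtures are tied to the gene universe of
#' the drug library so the stages compose end to end.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of written paths and the generated
#'   objects (`$fixtures`).
#' @export
simulate_inputs <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  ms <- gen_ms_fixture(cfg)
  utils::write.csv(ms$peaks, p("peaks.csv"), row.names = FALSE, quote = FALSE)
  utils::write.table(ms$library, p("compound_library.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tf <- gen_target_fixture(cfg)
  fp_df <- data.frame(
    id = names(tf$queries),
    bits = vapply(tf$queries, function(q) paste(q$bits, collapse = ","), ""),
    length = cfg$fp_length, stringsAsFactors = FALSE)
  utils::write.table(fp_df, p("fingerprints.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  drug_df <- data.frame(
    drug_id = names(tf$drugs),
    bits = vapply(tf$drugs, function(d)
      paste(d$fingerprint$bits, collapse = ","), ""),
    targets = vapply(tf$drugs, function(d)
      paste(d$targets, collapse = ";"), ""), stringsAsFactors = FALSE)
  utils::write.table(drug_df, p("drug_library.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gene_universe <- sort(unique(unlist(lapply(tf$drugs, `[[`, "targets"))))
  dis <- with_stream(cfg$seed, "world", {
    sort(c(sample(gene_universe, round(length(gene_universe) / 4)),
           sprintf("DGENE%03d", seq_len(80))))
  })
  nodes <- sort(union(gene_universe, dis))
  nf <- gen_network_fixture(cfg, nodes = nodes, targets = gene_universe,
                            disease_genes = dis)
  edge_out <- nf$edges
  edge_out$combined_score <- round(edge_out$confidence * 1000)
  utils::write.table(edge_out[, c("node_a", "node_b", "combined_score")],
                     p("edges.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(dis, p("disease_genes.txt"))
  ef <- gen_enrichment_fixture(cfg, universe = nodes)
  gmt <- vapply(names(ef$collection$sets), function(nm)
    paste(c(nm, "synthetic pathway", ef$collection$sets[[nm]]),
          collapse = "\t"), "")
  writeLines(gmt, p("gene_sets.gmt"))
  qf <- gen_qpcr_fixture(cfg)
  utils::write.csv(qf$ct, p("ct_table.csv"), row.names = FALSE, quote = FALSE)
  truth <- list(ms = ms$truth, target = tf$truth, network_hubs = nf$hubs,
                enrichment_planted = ef$planted, qpcr = qf$truth)
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns",
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    paths = list(peaks = p("peaks.csv"),
                 compound_library = p("compound_library.tsv"),
                 fingerprints = p("fingerprints.tsv"),
                 drug_library = p("drug_library.tsv"),
                 edges = p("edges.tsv"),
                 disease_genes = p("disease_genes.txt"),
                 gene_sets = p("gene_sets.gmt"),
                 ct_table = p("ct_table.csv"),
                 truth = p("truth.json")),
    fixtures = list(ms = ms, target = tf, network = nf, enrichment = ef,
                    qpcr = qf)))
}

run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e)
    stop("stage ", sQuote(name), " failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full network-pharmacology pipeline
#'
#' Executes annotate -> predict -> network (with hub refinement) ->
#' enrich, and qpcr when a Ct table is given; writes every intermediate
#' artifact plus a machine-readable JSON report with per-stage counts and
#' the compound -> target -> pathway provenance chains. Every output
#' records the config hash that produced it. Rerunning with the same
#' config and inputs is byte-identical.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, the report list (also written to
#'   `out_dir/report.json`).
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  # out_dir excluded: the hash identifies the analysis, not where it lands
  hash <- config_hash(unclass(cfg)[setdiff(names(cfg), "out_dir")])
  log_msg("INFO", "netpharm ", as.character(utils::packageVersion("netpharm")),
          " run; seed=", cfg$seed, " config=", hash)
  report <- list(package_version = as.character(utils::packageVersion("netpharm")),
                 seed = cfg$seed, config_hash = hash, counts = list(),
                 provenance = list())
  agg <- NULL
  sel <- NULL
  enr <- NULL

  if ("annotate" %in% cfg$stages && !is.null(cfg$peaks)) {
    ann <- run_stage("annotate", {
      peaks <- read_peak_table(cfg$peaks)
      lib <- read_compound_library(cfg$compound_library)
      annotate_peaks(peaks, lib, tol = cfg$tol)
    })
    write_annotations(ann, file.path(cfg$out_dir, "annotations.tsv"))
    report$counts$annotated_peaks <- length(unique(ann$peak))
    report$counts$annotated_compounds <- length(unique(ann$compound_id))
    log_msg("INFO", "annotate: ", nrow(ann), " annotations over ",
            report$counts$annotated_peaks, " peaks")
  }

  if ("predict" %in% cfg$stages && !is.null(cfg$fingerprints)) {
    preds <- run_stage("predict", {
      fps <- read_fingerprints(cfg$fingerprints)
      drugs <- read_drug_library(cfg$drug_library)
      do.call(rbind, lapply(fps, predict_targets, drugs = drugs,
                            threshold = cfg$similarity_threshold))
    })
    if (is.null(preds))
      preds <- data.frame(compound_id = character(0), gene = character(0),
                          max_similarity = numeric(0),
                          supporting_drugs = character(0))
    rownames(preds) <- NULL
    agg <- aggregate_targets(preds)
    write_predictions(preds, file.path(cfg$out_dir, "predictions.tsv"))
    utils::write.table(agg, file.path(cfg$out_dir, "putative_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$counts$predicted_targets <- nrow(agg)
    log_msg("INFO", "predict: ", nrow(agg), " putative targets")
  }

  if ("network" %in% cfg$stages && !is.null(cfg$edges)) {
    netres <- run_stage("network", {
      dis <- toupper(readLines(cfg$disease_genes))
      dis <- dis[nzchar(dis)]
      targets <- if (!is.null(agg)) agg$gene else character(0)
      net <- build_network(targets, dis, read_edge_list(cfg$edges),
                           min_conf = cfg$min_conf)
      cen <- centralities(net)
      hubs <- select_hubs(cen)
      major <- refine_major_hubs(net, hubs)
      s <- classify_candidates(major, net, hubs = hubs, provenance = agg)
      write_sif(net, file.path(cfg$out_dir, "network.sif"))
      write_node_attributes(net, s, file.path(cfg$out_dir, "node_attributes.tsv"))
      list(sel = s, nodes = igraph::vcount(net$graph),
           edges = igraph::ecount(net$graph))
    })
    sel <- netres$sel
    report$counts$nodes <- netres$nodes
    report$counts$edges <- netres$edges
    report$counts$hubs <- length(sel$hubs)
    report$counts$major_hubs <- length(sel$major_hubs)
    report$counts$candidate_targets <- length(sel$candidate_targets)
    log_msg("INFO", "network: ", report$counts$nodes, " nodes, ",
            report$counts$edges, " edges; ", report$counts$hubs, " hubs -> ",
            report$counts$major_hubs, " major hubs")
  }

  if ("enrich" %in% cfg$stages && !is.null(cfg$gene_sets) &&
      !is.null(sel) && length(sel$candidate_targets)) {
    enr <- run_stage("enrich", {
      coll <- read_gmt(cfg$gene_sets)
      suppressWarnings(run_enrichment(sel$candidate_targets, coll,
                                      alpha = cfg$alpha))
    })
    write_enrichment(enr, file.path(cfg$out_dir, "enrichment.tsv"))
    report$counts$significant_pathways <- sum(enr$significant)
    log_msg("INFO", "enrich: ", sum(enr$significant), " significant pathways")
  }

  if ("qpcr" %in% cfg$stages && !is.null(cfg$ct_table)) {
    rel <- run_stage("qpcr", {
      relative_expression(read_ct_table(cfg$ct_table),
                          ref_gene = cfg$ref_gene,
                          control_group = cfg$control_group)
    })
    utils::write.csv(rel, file.path(cfg$out_dir, "qpcr_fold_changes.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summarize_folds(rel),
                     file.path(cfg$out_dir, "qpcr_group_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    report$counts$qpcr_genes <- length(unique(rel$gene))
  }

  # compound -> target -> pathway provenance chains
  if (!is.null(sel) && !is.null(sel$provenance) && !is.null(enr)) {
    sig_sets <- enr$name[enr$significant]
    if (length(sig_sets)) {
      coll <- read_gmt(cfg$gene_sets)
      chains <- list()
      for (gene in sel$provenance$gene) {
        paths <- sig_sets[vapply(sig_sets, function(s)
          gene %in% coll$sets[[s]], logical(1))]
        if (length(paths)) {
          cmpds <- strsplit(
            sel$provenance$compounds[sel$provenance$gene == gene], ";")[[1]]
          for (cm in cmpds) for (pw in paths)
            chains[[length(chains) + 1L]] <-
              list(compound = cm, target = gene, pathway = pw)
        }
      }
      report$provenance <- chains
    }
  }

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
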