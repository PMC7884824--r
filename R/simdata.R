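# Seeded generators for every input the pipeline consumes. Each generator
# draws from its own RNG stream, derived from the master seed by a stable
# label, so adding a generator never shifts another's output; each fixture
# carries its truth so downstream tests are self-checking.

# stable 32-bit sub-seed from (seed, label); exact in double arithmetic
label_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

with_stream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(label_seed(seed, label))
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with realistic
#' defaults: small-metabolite element ranges, 2 ppm mass noise (routine for
#' a modern QTOF), 1024-bit fingerprints at 0.3 density with a 5% query
#' flip rate, a 400-node interaction network with mean background degree 4
#' and 10 planted degree-40 hubs, 50 gene sets of 20 genes over a
#' 2000-gene universe with one planted enriched set, and a three-group
#' six-animal qPCR design with 0.1-cycle replicate noise.
#'
#' @param seed Master seed; every generator derives its own stream from it.
#' @param n_compounds Compound library size for the MS fixture.
#' @param element_ranges Named list of `c(min, max)` element counts.
#' @param ppm_sigma Gaussian m/z noise, ppm.
#' @param fp_length,fp_density Fingerprint length and fraction of set bits.
#' @param flip_rate Per-position flip probability for query fingerprints.
#' @param n_drugs,targets_per_drug,n_target_genes Drug library shape.
#' @param n_queries Number of query compounds in the target fixture.
#' @param ppi_nodes,bg_mean_degree Background Erdos-Renyi shape.
#' @param n_hubs,hub_degree Planted overlay stars.
#' @param frac_low_conf Fraction of edge confidences drawn below 0.4.
#' @param n_sets,set_size,universe_size,query_size,elevation Enrichment
#'   fixture shape; `elevation` is the probability a query gene comes from
#'   the planted set.
#' @param qpcr_n Samples per group.
#' @param qpcr_folds Named list (group -> named numeric per gene) of
#'   planted fold changes relative to the control group.
#' @param ct_sigma Replicate noise on the Ct scale (cycles).
#' @param n_replicates Technical qPCR replicates.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_compounds = 500,
                       element_ranges = list(C = c(4, 30), H = c(4, 40),
                                             N = c(0, 3), O = c(0, 10),
                                             S = c(0, 1)),
                       ppm_sigma = 2,
                       fp_length = 1024, fp_density = 0.3, flip_rate = 0.05,
                       n_drugs = 50, targets_per_drug = 5,
                       n_target_genes = 300, n_queries = 20,
                       ppi_nodes = 400, bg_mean_degree = 4,
                       n_hubs = 10, hub_degree = 40, frac_low_conf = 0.3,
                       n_sets = 50, set_size = 20, universe_size = 2000,
                       query_size = 40, elevation = 0.6,
                       qpcr_n = 6,
                       qpcr_folds = list(
                         model = c(AKT1 = 0.4, VEGFA = 2.5, ERBB2 = 2.0, AR = 1.6),
                         treated = c(AKT1 = 0.8, VEGFA = 1.4, ERBB2 = 1.2, AR = 1.1)),
                       ct_sigma = 0.1, n_replicates = 3) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_compounds > 0, cfg$ppm_sigma >= 0,
            cfg$fp_density > 0, cfg$fp_density <= 1,
            cfg$flip_rate >= 0, cfg$flip_rate <= 1,
            cfg$frac_low_conf >= 0, cfg$frac_low_conf <= 1,
            cfg$elevation >= 0, cfg$elevation <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a compound library and matching peak table
#'
#' Samples molecular formulas within the configured element ranges, picks
#' one adduct per compound, and emits one peak at the theoretical adduct
#' m/z perturbed by Gaussian ppm noise. The truth map records the
#' generating (compound, adduct) pair for every peak.
#'
#' @param cfg A [sim_config()].
#' @return List with `library` (id, name, formula), `peaks` (rt_min, mz,
#'   polarity, intensity) and `truth` (peak, compound_id, adduct).
#' @export
gen_ms_fixture <- function(cfg) {
  with_stream(cfg$seed, "ms", {
    n <- cfg$n_compounds
    er <- cfg$element_ranges
    formulas <- vapply(seq_len(n), function(i) {
      counts <- vapply(er, function(r) {
        as.integer(sample(seq(r[1], r[2]), 1))
      }, integer(1))
      names(counts) <- names(er)
      format_formula(counts[counts > 0])
    }, character(1))
    lib <- data.frame(id = sprintf("cmp%04d", seq_len(n)),
                      name = sprintf("compound %d", seq_len(n)),
                      formula = formulas, stringsAsFactors = FALSE)
    rules <- default_adducts()
    ri <- sample(nrow(rules), n, replace = TRUE)
    theo <- vapply(seq_len(n), function(i)
      adduct_mz(lib$formula[i], rules[ri[i], ]), numeric(1))
    mz <- theo * (1 + stats::rnorm(n, 0, cfg$ppm_sigma) / 1e6)
    peaks <- data.frame(rt_min = round(stats::runif(n, 0.5, 20), 2), mz = mz,
                        polarity = rules$polarity[ri],
                        intensity = round(stats::rlnorm(n, 10, 1)),
                        stringsAsFactors = FALSE)
    truth <- data.frame(peak = seq_len(n), compound_id = lib$id,
                        adduct = rules$name[ri], stringsAsFactors = FALSE)
    list(library = lib, peaks = peaks, truth = truth)
  })
}

#' Simulate a drug library and query fingerprints
#'
#' Drugs get random bit sets at the configured density and random target
#' genes; each query is a randomly chosen drug's fingerprint with every
#' bit position flipped independently at `flip_rate`. The truth map
#' records each query's source drug.
#'
#' @param cfg A [sim_config()].
#' @return List with `drugs` (list of [drug_record()]), `queries` (list of
#'   [fingerprint()]) and `truth` (query_id, source_drug).
#' @export
gen_target_fixture <- function(cfg) {
  with_stream(cfg$seed, "target", {
    L <- cfg$fp_length
    genes <- sprintf("G%04d", seq_len(cfg$n_target_genes))
    nbits <- round(cfg$fp_density * L)
    drugs <- lapply(seq_len(cfg$n_drugs), function(i) {
      id <- sprintf("drug%03d", i)
      drug_record(id, fingerprint(id, sample(0:(L - 1), nbits)),
                  sample(genes, cfg$targets_per_drug))
    })
    names(drugs) <- vapply(drugs, `[[`, "", "drug_id")
    src <- sample(cfg$n_drugs, cfg$n_queries, replace = TRUE)
    queries <- lapply(seq_len(cfg$n_queries), function(i) {
      bits <- drugs[[src[i]]]$fingerprint$bits
      flip <- which(stats::runif(L) < cfg$flip_rate) - 1L
      new_bits <- sort(c(setdiff(bits, flip), setdiff(flip, bits)))
      fingerprint(sprintf("query%03d", i), new_bits, length = L)
    })
    names(queries) <- vapply(queries, `[[`, "", "id")
    truth <- data.frame(query_id = names(queries),
                        source_drug = names(drugs)[src],
                        stringsAsFactors = FALSE)
    list(drugs = drugs, queries = queries, truth = truth)
  })
}

#' Simulate a confidence-scored interaction network with planted hubs
#'
#' Erdos-Renyi background at the configured mean degree, plus overlay
#' stars centered on the planted hubs. Edge confidences are drawn so that
#' `frac_low_conf` of them fall below 0.4. Node roles (putative target /
#' disease gene / both) are assigned at random.
#'
#' @param cfg A [sim_config()].
#' @param nodes Optional node name vector; defaults to `cfg$ppi_nodes`
#'   synthetic gene names (useful to tie the network to genes produced by
#'   the other fixtures).
#' @param targets,disease_genes Optional role assignment; by default roles
#'   are drawn at random (~45% target-only, ~45% disease-only, ~10% both).
#' @return List with `edges` (node_a, node_b, confidence), `targets`,
#'   `disease_genes` (character vectors) and `hubs` (planted hub names).
#' @export
gen_network_fixture <- function(cfg, nodes = NULL, targets = NULL,
                                disease_genes = NULL) {
  with_stream(cfg$seed, "network", {
    if (is.null(nodes)) nodes <- sprintf("N%04d", seq_len(cfg$ppi_nodes))
    n <- length(nodes)
    if (is.null(targets) || is.null(disease_genes)) {
      r <- stats::runif(n)
      targets <- nodes[r < 0.55]
      disease <- nodes[r >= 0.45]
    } else {
      disease <- disease_genes
    }
    p <- min(1, cfg$bg_mean_degree / (n - 1))
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    bg <- pairs[, keep, drop = FALSE]
    hubs <- sample(nodes, cfg$n_hubs)
    # leaves are drawn from recycled random permutations of the non-hub
    # nodes, so no leaf lands in many stars and the planted centers stay
    # the unambiguous degree outliers
    pool <- setdiff(seq_len(n), match(hubs, nodes))
    total <- cfg$n_hubs * min(cfg$hub_degree, length(pool))
    perm <- unlist(lapply(seq_len(ceiling(total / length(pool))),
                          function(i) sample(pool)))
    star <- lapply(seq_len(cfg$n_hubs), function(i) {
      k <- min(cfg$hub_degree, length(pool))
      leaves <- unique(perm[seq((i - 1) * k + 1, i * k)])
      rbind(rep(match(hubs[i], nodes), length(leaves)), leaves)
    })
    all_e <- cbind(bg, do.call(cbind, star))
    a <- pmin(all_e[1, ], all_e[2, ])
    b <- pmax(all_e[1, ], all_e[2, ])
    dup <- duplicated(paste(a, b))
    a <- a[!dup]; b <- b[!dup]
    m <- length(a)
    low <- stats::runif(m) < cfg$frac_low_conf
    conf <- ifelse(low, stats::runif(m, 0, 0.4 - 1e-9),
                   stats::runif(m, 0.4, 1))
    list(edges = data.frame(node_a = nodes[a], node_b = nodes[b],
                            confidence = conf, stringsAsFactors = FALSE),
         targets = targets, disease_genes = disease, hubs = sort(hubs))
  })
}

#' Simulate a gene-set collection with one planted enriched set
#'
#' Query genes are drawn from the planted set with probability
#' `elevation`, from the rest of the universe otherwise.
#'
#' @param cfg A [sim_config()].
#' @param universe Optional background gene universe; defaults to
#'   `cfg$universe_size` synthetic gene names.
#' @return List with `collection` (a [gene_set_collection()]), `query`
#'   (character vector) and `planted` (the enriched set's name).
#' @export
gen_enrichment_fixture <- function(cfg, universe = NULL) {
  with_stream(cfg$seed, "enrich", {
    if (is.null(universe)) universe <- sprintf("U%04d", seq_len(cfg$universe_size))
    stopifnot(length(universe) > cfg$set_size)
    sets <- lapply(seq_len(cfg$n_sets), function(i)
      sample(universe, cfg$set_size))
    names(sets) <- sprintf("set%02d", seq_len(cfg$n_sets))
    planted <- names(sets)[1]
    from_planted <- stats::runif(cfg$query_size) < cfg$elevation
    q_planted <- sample(sets[[planted]],
                        min(sum(from_planted), cfg$set_size))
    q_bg <- sample(setdiff(universe, q_planted),
                   cfg$query_size - length(q_planted))
    coll <- gene_set_collection(sets, background = universe)
    list(collection = coll, query = sample(c(q_planted, q_bg)),
         planted = planted)
  })
}

#' Simulate a qPCR Ct table with planted fold changes
#'
#' Target-gene Ct values are a per-gene baseline minus log2 of the planted
#' group fold, plus Gaussian replicate noise; the reference gene sits at a
#' fixed baseline with the same noise. Control-group folds are 1 by
#' construction.
#'
#' @param cfg A [sim_config()].
#' @return List with `ct` (sample, group, gene, ct, replicate) and `truth`
#'   (group, gene, fold).
#' @export
gen_qpcr_fixture <- function(cfg) {
  with_stream(cfg$seed, "qpcr", {
    genes <- names(cfg$qpcr_folds[[1]])
    groups <- c("control", names(cfg$qpcr_folds))
    base_ct <- stats::setNames(stats::runif(length(genes), 22, 28), genes)
    ref_ct <- 18
    rows <- list()
    for (g in groups) {
      folds <- if (g == "control")
        stats::setNames(rep(1, length(genes)), genes) else cfg$qpcr_folds[[g]]
      for (i in seq_len(cfg$qpcr_n)) {
        sid <- sprintf("%s_%02d", g, i)
        for (gene in c("ACTB", genes)) {
          mu <- if (gene == "ACTB") ref_ct else base_ct[[gene]] - log2(folds[[gene]])
          for (rep_i in seq_len(cfg$n_replicates)) {
            rows[[length(rows) + 1L]] <- data.frame(
              sample = sid, group = g, gene = gene,
              ct = mu + stats::rnorm(1, 0, cfg$ct_sigma),
              replicate = rep_i, stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth <- do.call(rbind, lapply(names(cfg$qpcr_folds), function(g)
      data.frame(group = g, gene = genes,
                 fold = as.numeric(cfg$qpcr_folds[[g]][genes]),
                 stringsAsFactors = FALSE)))
    list(ct = do.call(rbind, rows), truth = truth)
  })
}
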