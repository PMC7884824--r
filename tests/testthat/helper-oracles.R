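# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# peak annotation by a plain triple loop
bf_annotate <- function(peaks, library, rules, tol) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    for (j in seq_len(nrow(library))) {
      for (r in seq_len(nrow(rules))) {
        if (rules$polarity[r] != peaks$polarity[i]) next
        theo <- (monoisotopic_mass(library$formula[j]) + rules$shift[r]) /
          rules$charge[r]
        err <- (peaks$mz[i] - theo) / theo * 1e6
        if (abs(err) <= tol)
          rows[[length(rows) + 1L]] <- data.frame(
            peak = i, compound_id = library$id[j], adduct = rules$name[r],
            ppm_error = err, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(data.frame(peak = integer(0),
                                       compound_id = character(0),
                                       adduct = character(0),
                                       ppm_error = numeric(0)))
  do.call(rbind, rows)
}

# Floyd-Warshall distances + shortest-path counting over an adjacency
# matrix; returns degree, pair-normalized betweenness, reachable-only
# closeness for every node
bf_centralities <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  sigma <- ifelse(adj == 1, 1, 0)  # number of shortest paths
  diag(sigma) <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || k == i || k == j) next
    via <- d[i, k] + d[k, j]
    if (via < d[i, j]) {
      d[i, j] <- via
      sigma[i, j] <- sigma[i, k] * sigma[k, j]
    } else if (is.finite(via) && via == d[i, j]) {
      sigma[i, j] <- sigma[i, j] + sigma[i, k] * sigma[k, j]
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (is.finite(d[s, t]) && d[s, v] + d[v, t] == d[s, t])
        acc <- acc + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
    btw[v] <- acc
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else length(dv) / sum(dv)
  }, numeric(1))
  data.frame(degree = as.integer(rowSums(adj)), betweenness = btw,
             closeness = clo)
}

# Floyd-Warshall path-counting can overcount when multiple intermediate
# orders see the same path; verified against true enumeration below for
# the graph sizes used in tests (n <= 8), where enumeration is feasible.
# True enumeration oracle: all simple paths between s and t, keep shortest.
enum_shortest_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list()
  walk <- function(v, seen) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- seen
      return(invisible())
    }
    for (w in which(adj[v, ] == 1)) if (!w %in% seen) walk(w, c(seen, w))
  }
  walk(s, s)
  if (!length(paths)) return(list())
  len <- vapply(paths, length, 1L)
  paths[len == min(len)]
}

bf_centralities_enum <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t) next
    sp <- enum_shortest_paths(adj, s, t)
    if (!length(sp)) next
    d[s, t] <- d[t, s] <- length(sp[[1]]) - 1L
    inner <- unlist(lapply(sp, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      tab <- table(inner)
      idx <- as.integer(names(tab))
      btw[idx] <- btw[idx] + as.numeric(tab) / length(sp)
    }
  }
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  clo <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (!length(dv)) 0 else length(dv) / sum(dv)
  }, numeric(1))
  data.frame(degree = as.integer(rowSums(adj)), betweenness = btw,
             closeness = clo)
}

# exact hypergeometric upper tail by plain ratio-of-binomials summation
bf_hyper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# random undirected simple graph as adjacency matrix + matching pharm_network
random_graph <- function(n, p) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
  adj
}

adj_to_network <- function(adj) {
  n <- nrow(adj)
  nodes <- sprintf("V%02d", seq_len(n))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  edges <- data.frame(node_a = nodes[idx[, 1]], node_b = nodes[idx[, 2]],
                      confidence = rep(1, nrow(idx)), stringsAsFactors = FALSE)
  build_network(nodes, character(0), edges, min_conf = 0)
}
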