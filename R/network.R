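#' Build the putative-target / disease-gene interaction network
#'
#' Nodes are the union of the putative target set and the disease gene set,
#' with role `putative_target`, `disease_gene`, or `both`. Edges are kept
#' when their confidence is at least `min_conf`, both endpoints are in the
#' node universe, and they are not self-loops; duplicate edges are
#' collapsed. The graph is undirected and simple.
#'
#' @param targets Character vector of putative target gene symbols.
#' @param disease_genes Character vector of disease-associated gene symbols.
#' @param edges data.frame with columns `node_a`, `node_b`, `confidence`
#'   (in \[0, 1\]; see [read_edge_list()] for the 0-1000 input convention).
#' @param min_conf Minimum combined confidence; 0.4 ("medium") is the
#'   conventional default.
#' @return Object of class `pharm_network`: list with `graph` (igraph,
#'   undirected simple, includes isolated nodes) and `roles` (named
#'   character vector over all nodes).
#' @export
build_network <- function(targets, disease_genes, edges, min_conf = 0.4) {
  stopifnot(min_conf >= 0, min_conf <= 1)
  targets <- unique(toupper(targets))
  disease_genes <- unique(toupper(disease_genes))
  nodes <- union(targets, disease_genes)
  if (!length(nodes)) stop("empty node universe")
  roles <- ifelse(nodes %in% targets & nodes %in% disease_genes, "both",
                  ifelse(nodes %in% targets, "putative_target", "disease_gene"))
  names(roles) <- nodes
  e <- edges
  e$node_a <- toupper(e$node_a)
  e$node_b <- toupper(e$node_b)
  keep <- e$confidence >= min_conf & e$node_a %in% nodes & e$node_b %in% nodes &
    e$node_a != e$node_b
  e <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("node_a", "node_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g, roles = roles), class = "pharm_network")
}

#' @export
print.pharm_network <- function(x, ...) {
  cat("pharm_network:", igraph::vcount(x$graph), "nodes,",
      igraph::ecount(x$graph), "edges\n")
  cat("roles:", paste(names(table(x$roles)), table(x$roles),
                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Degree, betweenness and closeness of every node
#'
#' Degree is the incident edge count. Betweenness is shortest-path
#' betweenness on the undirected, unweighted graph, normalized by
#' `(n-1)(n-2)/2` node pairs. Closeness follows the within-component
#' convention: (number of reachable nodes) / (sum of shortest-path
#' distances to them), and 0 for an isolated node. Under uniform
#' application, the normalization choice cannot change median-threshold
#' outcomes downstream.
#'
#' @param net A `pharm_network` or an igraph graph.
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centralities <- function(net) {
  g <- if (inherits(net, "pharm_network")) net$graph else net
  n <- igraph::vcount(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  d <- igraph::distances(g)
  clo <- apply(d, 1, function(row) {
    reach <- row[is.finite(row) & row > 0]
    if (!length(reach)) 0 else length(reach) / sum(reach)
  })
  data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
             betweenness = as.numeric(btw), closeness = as.numeric(clo),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select hub nodes by the 2x-median degree rule
#'
#' Hubs are the nodes whose degree is strictly greater than twice the
#' median degree over all nodes (median of an even-length list is the mean
#' of the two central order statistics). With all degrees equal, no node
#' qualifies.
#'
#' @param records Centrality data.frame from [centralities()].
#' @return Character vector of hub node names.
#' @export
select_hubs <- function(records) {
  stopifnot(nrow(records) > 0)
  records$node[records$degree > 2 * stats::median(records$degree)]
}

#' Refine hubs to major hubs by the triple-median rule
#'
#' Induces the hub subnetwork from direct hub-hub edges, recomputes all
#' three centralities on it, and keeps the nodes whose degree AND
#' betweenness AND closeness each strictly exceed the respective median
#' over the hub subnetwork. The medians are those of the hub-induced
#' subnetwork, not the full network, because the topological parameters
#' are recomputed after the hub network is built.
#'
#' @param net A `pharm_network`.
#' @param hubs Character vector of hub node names (subset of the network's
#'   nodes).
#' @return Character vector of major-hub node names (empty for an empty
#'   hub set, a single hub, or any vertex-transitive hub subnetwork, since
#'   no node can strictly exceed its own median there).
#' @export
refine_major_hubs <- function(net, hubs) {
  g <- if (inherits(net, "pharm_network")) net$graph else net
  stopifnot(all(hubs %in% igraph::V(g)$name))
  if (!length(hubs)) return(character(0))
  sub <- igraph::induced_subgraph(g, hubs)
  cen <- centralities(sub)
  keep <- cen$degree > stats::median(cen$degree) &
    cen$betweenness > stats::median(cen$betweenness) &
    cen$closeness > stats::median(cen$closeness)
  cen$node[keep]
}

#' Classify major hubs into candidate targets and disease genes
#'
#' Partitions the major hubs by node role. A node with role `both` is
#' counted in BOTH subsets (dual counting is deliberate and flagged in the
#' result; collapsing it silently would hide the overlap).
#'
#' @param major Character vector of major-hub node names.
#' @param net The `pharm_network` the hubs came from.
#' @param hubs Optional full hub set for bookkeeping.
#' @param provenance Optional data.frame from [aggregate_targets()] linking
#'   genes back to predicting compounds.
#' @return Object of class `hub_selection`: list with `hubs`,
#'   `major_hubs`, `candidate_targets` (major hubs whose role includes
#'   putative_target), `disease_subset` (role includes disease_gene),
#'   `dual_role` (role both), and `provenance` (NULL or the per-gene
#'   compound provenance restricted to candidates).
#' @export
classify_candidates <- function(major, net, hubs = major, provenance = NULL) {
  stopifnot(all(major %in% names(net$roles)))
  role <- net$roles[major]
  cand <- major[role %in% c("putative_target", "both")]
  dis <- major[role %in% c("disease_gene", "both")]
  prov <- NULL
  if (!is.null(provenance))
    prov <- provenance[provenance$gene %in% cand, , drop = FALSE]
  structure(list(hubs = hubs, major_hubs = major, candidate_targets = cand,
                 disease_subset = dis, dual_role = major[role == "both"],
                 provenance = prov),
            class = "hub_selection")
}

#' @export
print.hub_selection <- function(x, ...) {
  cat("hub_selection:", length(x$hubs), "hubs;", length(x$major_hubs),
      "major hubs;", length(x$candidate_targets), "candidate targets;",
      length(x$disease_subset), "disease genes (",
      length(x$dual_role), "dual-role, counted in both )\n")
  invisible(x)
}
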