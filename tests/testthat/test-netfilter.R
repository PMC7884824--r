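# netfilter: network construction, centralities, two-stage hub filter

test_that("build_network assigns roles and filters edges like a brute-force count", {
  edges <- data.frame(node_a = c("A", "A", "B", "C", "A", "Z"),
                      node_b = c("B", "C", "C", "C", "A", "B"),
                      confidence = c(0.9, 0.3, 0.5, 0.8, 0.9, 0.99))
  net <- build_network(c("A", "B"), c("B", "C"), edges, min_conf = 0.4)
  expect_setequal(names(net$roles), c("A", "B", "C"))
  expect_identical(unname(net$roles[c("A", "B", "C")]),
                   c("putative_target", "both", "disease_gene"))
  # kept: A-B (0.9), B-C (0.5); dropped: conf 0.3, self-loop C-C and A-A,
  # Z outside universe
  expect_equal(igraph::ecount(net$graph), 2)
  # all edges below threshold -> edgeless network over the universe
  net0 <- build_network("A", "B", edges[edges$confidence < 0.2, ], 0.4)
  expect_equal(igraph::ecount(net0$graph), 0)
  expect_equal(igraph::vcount(net0$graph), 2)
  expect_error(build_network(character(0), character(0), edges), "empty node")
  # random fixture: kept-edge count equals the brute-force filter count
  set.seed(9)
  nodes <- sprintf("N%02d", 1:50)
  e <- data.frame(node_a = sample(nodes, 300, TRUE),
                  node_b = sample(nodes, 300, TRUE),
                  confidence = runif(300))
  net <- build_network(nodes[1:30], nodes[20:50], e, 0.4)
  keep <- e$confidence >= 0.4 & e$node_a != e$node_b
  want <- unique(t(apply(cbind(e$node_a, e$node_b)[keep, ], 1, sort)))
  expect_equal(igraph::ecount(net$graph), nrow(want))
})

test_that("centralities on canonical graphs", {
  # star S4: center degree 4, betweenness 1 (normalized), leaves 0
  star_edges <- data.frame(node_a = "HUB", node_b = paste0("L", 1:4),
                           confidence = 1)
  net <- build_network(c("HUB", paste0("L", 1:4)), character(0), star_edges, 0)
  cen <- centralities(net)
  hub <- cen[cen$node == "HUB", ]
  expect_equal(hub$degree, 4L)
  expect_equal(hub$betweenness, 1)
  expect_equal(cen$betweenness[cen$node != "HUB"], rep(0, 4))
  expect_equal(hub$closeness, 1) # distance 1 to all four leaves
  # path P3: middle betweenness 1 normalized
  p3 <- build_network(c("A", "B", "C"), character(0),
                      data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
                                 confidence = 1), 0)
  cenp <- centralities(p3)
  expect_equal(cenp$betweenness[cenp$node == "B"], 1)
  # isolated node closeness is 0
  iso <- build_network(c("A", "B"), character(0),
                       data.frame(node_a = character(0),
                                  node_b = character(0),
                                  confidence = numeric(0)), 0)
  expect_equal(centralities(iso)$closeness, c(0, 0))
})

test_that("centralities equal the exhaustive shortest-path oracles on random graphs", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    adj <- random_graph(n, sample(c(0.2, 0.35, 0.5), 1))
    net <- adj_to_network(adj)
    got <- centralities(net)
    got <- got[order(got$node), ]
    want <- bf_centralities(adj)
    expect_equal(got$degree, want$degree)
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-10)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-10)
    if (i <= 40) { # true path-enumeration oracle on a subset (slower)
      want2 <- bf_centralities_enum(adj)
      expect_equal(got$betweenness, want2$betweenness, tolerance = 1e-10)
      expect_equal(got$closeness, want2$closeness, tolerance = 1e-10)
    }
  }
})

test_that("select_hubs applies the strict 2x-median rule", {
  rec <- function(deg) data.frame(node = sprintf("n%d", seq_along(deg)),
                                  degree = deg, betweenness = 0, closeness = 0)
  expect_length(select_hubs(rec(rep(3, 6))), 0)           # ties excluded
  expect_identical(select_hubs(rec(c(1, 1, 1, 1, 10))), "n5")
  expect_identical(select_hubs(rec(c(1, 2, 3, 10))), "n4") # even-count median 2.5
  # at most ceil(n/2) nodes can exceed the median-based cut
  set.seed(3)
  for (i in 1:30) {
    deg <- sample(0:30, sample(3:25, 1), replace = TRUE)
    expect_lte(length(select_hubs(rec(deg))), ceiling(length(deg) / 2))
  }
})

test_that("select_hubs is invariant under node relabeling", {
  set.seed(13)
  adj <- random_graph(10, 0.3)
  net <- adj_to_network(adj)
  hubs <- select_hubs(centralities(net))
  perm <- sample(10)
  adj2 <- adj[perm, perm]
  net2 <- adj_to_network(adj2)
  hubs2 <- select_hubs(centralities(net2))
  # node i in net2 corresponds to node perm[i] in net
  expect_setequal(sprintf("V%02d", perm[as.integer(sub("V", "", hubs2))]), hubs)
})

test_that("refine_major_hubs: degenerate and vertex-transitive cases are empty", {
  k4_edges <- do.call(rbind, lapply(combn(4, 2, simplify = FALSE), function(p)
    data.frame(node_a = paste0("K", p[1]), node_b = paste0("K", p[2]),
               confidence = 1)))
  net <- build_network(paste0("K", 1:4), character(0), k4_edges, 0)
  expect_length(refine_major_hubs(net, paste0("K", 1:4)), 0) # clique: all tie
  expect_length(refine_major_hubs(net, "K1"), 0)             # single hub
  expect_length(refine_major_hubs(net, character(0)), 0)
  # cycle C6 (vertex-transitive)
  c6 <- data.frame(node_a = paste0("C", 1:6),
                   node_b = paste0("C", c(2:6, 1)), confidence = 1)
  netc <- build_network(paste0("C", 1:6), character(0), c6, 0)
  expect_length(refine_major_hubs(netc, paste0("C", 1:6)), 0)
})

test_that("refine_major_hubs matches a brute-force triple-median evaluation", {
  set.seed(55)
  for (rep in 1:10) {
    # dense core + sparse periphery over 20 hubs
    n <- 20
    adj <- matrix(0L, n, n)
    core <- 1:7
    for (i in core) for (j in core) if (i < j && runif(1) < 0.9)
      adj[i, j] <- adj[j, i] <- 1L
    for (i in 1:n) for (j in 1:n)
      if (i < j && (i > 7 || j > 7) && runif(1) < 0.08)
        adj[i, j] <- adj[j, i] <- 1L
    net <- adj_to_network(adj)
    hubs <- igraph::V(net$graph)$name
    got <- refine_major_hubs(net, hubs)
    want <- {
      cen <- bf_centralities(adj)
      nodes <- sprintf("V%02d", 1:n)
      nodes[cen$degree > median(cen$degree) &
              cen$betweenness > median(cen$betweenness) &
              cen$closeness > median(cen$closeness)]
    }
    expect_setequal(got, want)
    expect_true(all(got %in% hubs))
    # returned nodes lean core-ward
    if (length(got)) expect_gte(mean(got %in% sprintf("V%02d", core)), 0.5)
  }
})

test_that("classify_candidates partitions by role with dual counting", {
  edges <- data.frame(node_a = "T1", node_b = "D1", confidence = 1)
  net <- build_network(c("T1", "B1"), c("D1", "B1"), edges, 0)
  sel <- classify_candidates(c("T1", "D1", "B1"), net)
  expect_setequal(sel$candidate_targets, c("T1", "B1"))
  expect_setequal(sel$disease_subset, c("D1", "B1"))
  expect_identical(sel$dual_role, "B1")
  # dual-role nodes are counted in both subsets
  expect_equal(length(sel$candidate_targets) + length(sel$disease_subset),
               3 + length(sel$dual_role))
  # all-disease major hubs -> no candidates
  sel2 <- classify_candidates("D1", net)
  expect_length(sel2$candidate_targets, 0)
})
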