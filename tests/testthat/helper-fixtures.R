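# Small graphs used across the suite, built in code.

# 4-node fixture: unit-weight edges {1-3, 1-4, 2-3, 2-4, 3-4};
# Laplacian spectrum {0, 2, 4, 4}; cells {1,2} and {3,4}.
f4_graph <- function() {
  A <- matrix(0, 4, 4)
  for (e in list(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))) {
    A[e[1], e[2]] <- 1
    A[e[2], e[1]] <- 1
  }
  weighted_graph(A)
}

# complete graph on n nodes, unit weights: spectrum {0, n, ..., n}
k_complete <- function(n, w = 1) {
  A <- matrix(w, n, n)
  diag(A) <- 0
  weighted_graph(A)
}

# path 1-2-3, unit weights
p3_graph <- function() {
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 1
  A[2, 3] <- A[3, 2] <- 1
  weighted_graph(A)
}

# connected Erdos-Renyi graph (regenerates until connected)
random_connected_gnp <- function(n, p, seed) {
  for (k in 0:50) {
    ig <- syncpath:::with_seed(seed + 131L * k, igraph::sample_gnp(n, p))
    if (igraph::is_connected(ig)) {
      A <- as.matrix(igraph::as_adjacency_matrix(ig, sparse = TRUE))
      return(weighted_graph(A))
    }
  }
  stop("no connected gnp graph found")
}

# same graph up to node order: labels agree as sets, weights agree after
# aligning by label
expect_same_graph <- function(g2, g, label = NULL) {
  testthat::expect_setequal(g2$labels, g$labels)
  testthat::expect_equal(g2$adjacency[g$labels, g$labels], g$adjacency,
                         tolerance = 1e-12, label = label)
}

# event node sets of a plan, as a list of sorted label vectors
plan_node_sets <- function(plan) {
  lapply(plan$events, function(ev) sort(ev$nodes))
}
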