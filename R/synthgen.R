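#' Specification of a planted cluster
#'
#' Describes one planted cluster for [planted_cluster_graph()]: `size` nodes
#' all attached (unit weight by default) to the same `external_degree` core
#' nodes, with internal topology `"empty"` (no internal edges; the planted
#' localized eigenvalue is then the external degree `m`, with multiplicity
#' `size - 1`) or `"clique"` (complete internal graph of weight
#' `internal_weight`; the localized eigenvalue shifts to
#' `m + size * internal_weight`).
#'
#' @param size number of cluster nodes (>= 2).
#' @param external_degree number of shared core attachment nodes (>= 1).
#' @param internal one of `"empty"`, `"clique"`.
#' @param internal_weight weight of internal edges for `"clique"`.
#' @return an object of class `cluster_spec`.
#' @export
cluster_spec <- function(size, external_degree, internal = c("empty", "clique"),
                         internal_weight = 1) {
  internal <- match.arg(internal)
  stopifnot(size >= 2L, external_degree >= 1L, internal_weight > 0)
  structure(list(size = as.integer(size),
                 external_degree = as.integer(external_degree),
                 internal = internal, internal_weight = internal_weight),
            class = "cluster_spec")
}

# localized eigenvalue contributed by a planted cluster
planted_eigenvalue <- function(spec) {
  if (spec$internal == "empty") as.numeric(spec$external_degree)
  else spec$external_degree + spec$size * spec$internal_weight
}

#' Generate a network with planted, analytically known clusters
#'
#' Builds a connected random core (Erdos-Renyi with
#' `p = 2*log(core_n)/core_n` by default, regenerated on disconnection up
#' to `max_retries` times) and attaches each planted cluster by connecting
#' every cluster node to the same randomly chosen set of core nodes.  By
#' construction every planted cluster is an external equitable cell, and
#' with empty internal topology it contributes `size - 1` degenerate
#' Laplacian eigenvalues equal to its external degree, with eigenvectors
#' supported on the cluster.
#'
#' @param core_n number of core nodes.
#' @param clusters list of [cluster_spec()]s.
#' @param p core edge probability (default `2*log(core_n)/core_n`).
#' @param core_graph optional [weighted_graph()] to use as the core instead
#'   of generating one.
#' @param seed RNG seed for core generation and attachment choice.
#' @param max_retries attempts at a connected core.
#' @param check_cells if `TRUE`, verify that [equitable_cells()] recovers
#'   exactly the planted cells (plus singletons) and regenerate on
#'   accidental extra cells.  Quadratic cost; meant for small fixtures.
#' @return an object of class `planted_graph`: `graph`, `ground_truth`
#'   (a `cell_partition` of the planted cells plus singletons), `expected`
#'   (data.frame: one row per cluster with its localized eigenvalue and
#'   multiplicity), `seed`, and `specs`.
#' @export
planted_cluster_graph <- function(core_n, clusters, p = NULL,
                                  core_graph = NULL, seed = 1L,
                                  max_retries = 20L, check_cells = FALSE) {
  stopifnot(length(clusters) >= 1L)
  if (inherits(clusters, "cluster_spec")) clusters <- list(clusters)
  lapply(clusters, function(cl) stopifnot(inherits(cl, "cluster_spec")))
  core_n <- as.integer(core_n)
  if (is.null(p)) p <- 2 * log(core_n) / core_n
  for (cl in clusters) {
    if (cl$external_degree > core_n) stop("external degree exceeds core size")
  }
  N <- core_n + sum(vapply(clusters, `[[`, 0L, "size"))
  for (attempt in seq_len(max_retries)) {
    built <- with_seed(seed + (attempt - 1L) * 1009L, {
      A_core <- if (!is.null(core_graph)) {
        stopifnot(n_nodes(core_graph) == core_n)
        core_graph$adjacency
      } else {
        ig <- igraph::sample_gnp(core_n, p)
        if (!igraph::is_connected(ig)) NULL else {
          as.matrix(igraph::as_adjacency_matrix(ig, sparse = TRUE))
        }
      }
      if (is.null(A_core)) NULL else {
        A <- matrix(0, N, N)
        A[seq_len(core_n), seq_len(core_n)] <- A_core
        at <- core_n
        cells <- list()
        for (cl in clusters) {
          nodes <- at + seq_len(cl$size)
          targets <- sample.int(core_n, cl$external_degree)
          A[nodes, targets] <- 1
          A[targets, nodes] <- 1
          if (cl$internal == "clique") {
            A[nodes, nodes] <- cl$internal_weight
            A[cbind(nodes, nodes)] <- 0
          }
          cells <- c(cells, list(nodes))
          at <- at + cl$size
        }
        list(A = A, cells = cells)
      }
    })
    if (is.null(built)) next
    g <- weighted_graph(built$A)
    planted <- lapply(built$cells, function(ix) g$labels[ix])
    singles <- as.list(g$labels[setdiff(seq_len(N), unlist(built$cells))])
    gt <- structure(list(cells = c(planted, singles), labels = g$labels),
                    class = "cell_partition")
    if (check_cells) {
      found <- equitable_cells(g)
      if (!same_partition(found, gt)) next  # accidental core cells: retry
    }
    expected <- data.frame(
      cluster = seq_along(clusters),
      size = vapply(clusters, `[[`, 0L, "size"),
      external_degree = vapply(clusters, `[[`, 0L, "external_degree"),
      eigenvalue = vapply(clusters, planted_eigenvalue, 0.0),
      multiplicity = vapply(clusters, `[[`, 0L, "size") - 1L)
    return(structure(list(graph = g, ground_truth = gt, expected = expected,
                          seed = seed, specs = clusters,
                          planted_cells = planted),
                     class = "planted_graph"))
  }
  stop("could not generate a valid planted graph in ", max_retries,
       " attempts (core disconnected or accidental extra cells)")
}

# partitions equal as sets of sets of labels
same_partition <- function(a, b) {
  ca <- sort(vapply(a$cells, function(x) paste(sort(x), collapse = ","), ""))
  cb <- sort(vapply(b$cells, function(x) paste(sort(x), collapse = ","), ""))
  identical(ca, cb)
}

#' @export
print.planted_graph <- function(x, ...) {
  cat(sprintf("planted_graph: N = %d, %d planted clusters\n",
              n_nodes(x$graph), nrow(x$expected)))
  print(x$expected)
  invisible(x)
}

#' Write the fixture manifest of a planted graph
#'
#' JSON manifest recording the seed, cluster specifications, ground-truth
#' cells and expected localized eigenvalues, for use alongside the graph
#' file written by [write_graph()].
#'
#' @param pg a [planted_cluster_graph()] result.
#' @param path output file.
#' @export
planted_manifest <- function(pg, path) {
  stopifnot(inherits(pg, "planted_graph"))
  obj <- list(
    seed = pg$seed,
    clusters = lapply(pg$specs, unclass),
    ground_truth_cells = lapply(pg$planted_cells, as.list),
    expected_eigenvalues = pg$expected)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' Orbit-structured weighted graph
#'
#' Builds a graph whose nodes fall into orbits: all nodes of an orbit are
#' mutually interchangeable (equal intra-orbit weights, equal weight to
#' every node of each other orbit).  Each orbit of size `k` with positive
#' internal/external weights contributes `k - 1` degenerate localized
#' Laplacian eigenvalues, so the transition plan proceeds orbit by orbit.
#'
#' @param orbit_sizes integer vector of orbit sizes.
#' @param inter_orbit_weights symmetric matrix (dim = number of orbits) of
#'   weights between orbits (diagonal ignored).
#' @param intra_orbit_weight vector of within-orbit weights (0 = no internal
#'   edges).
#' @return a [weighted_graph()] with labels `"1" ... "N"` ordered by orbit.
#' @export
orbit_weighted_graph <- function(orbit_sizes, inter_orbit_weights,
                                 intra_orbit_weight) {
  k <- length(orbit_sizes)
  inter_orbit_weights <- as.matrix(inter_orbit_weights)
  stopifnot(nrow(inter_orbit_weights) == k, ncol(inter_orbit_weights) == k,
            length(intra_orbit_weight) == k,
            all(inter_orbit_weights >= 0), all(intra_orbit_weight >= 0))
  if (max(abs(inter_orbit_weights - t(inter_orbit_weights))) > 0) {
    stop("inter_orbit_weights must be symmetric")
  }
  N <- sum(orbit_sizes)
  A <- matrix(0, N, N)
  ends <- cumsum(orbit_sizes)
  starts <- ends - orbit_sizes + 1L
  for (a in seq_len(k)) {
    ia <- starts[a]:ends[a]
    A[ia, ia] <- intra_orbit_weight[a]
    for (b in seq_len(k)) {
      if (a != b) A[ia, starts[b]:ends[b]] <- inter_orbit_weights[a, b]
    }
  }
  diag(A) <- 0
  weighted_graph(A)
}

#' The ten-node worked example
#'
#' An all-to-all connected weighted graph of 10 nodes with three symmetry
#' orbits \{1,2,3\}, \{4,5,6\} and \{7,8,9,10\}, constructed analytically so
#' that its Laplacian spectrum is exactly \{0, 1, 1, 1, 4, 4, 4, 6, 6, 6\}
#' and its transition plan is the orbit-by-orbit accretion sequence:
#' formation of \{7,8,9,10\} at relative coupling 1/6, growth by \{4,5,6\}
#' at 1/4, and complete synchronization at 1.  This is a synthetic stand-in
#' fixture with the same spectrum and event structure as the published
#' ten-node example (whose exact adjacency is not reproduced here); the
#' inter-orbit weights were solved from the orbit quotient so that the
#' quotient eigenvector at eigenvalue 1 is constant across the second and
#' third orbits, which is what makes the second event a growth of the
#' existing cluster rather than a separate formation.
#'
#' @return a [weighted_graph()] of 10 nodes.
#' @export
ten_node_orbit_graph <- function() {
  W <- matrix(c(0,      0.1,     0.1,
                0.1,    0,       37 / 70,
                0.1,    37 / 70, 0), 3L, 3L)
  orbit_weighted_graph(orbit_sizes = c(3L, 3L, 4L),
                       inter_orbit_weights = W,
                       intra_orbit_weight = c(0.1, 37 / 70, 36 / 35))
}

#' Count eigenvalues with eigenvectors supported on a node set
#'
#' Counts how many eigenvalues within `value_tol` of `value` have
#' eigenvectors whose support is confined to `nodes` — more precisely, the
#' dimension of the subspace of the (near-)degenerate eigenspace that is
#' supported on the node set, which is basis-invariant under rotations
#' inside the block (the eigensolver returns an arbitrary basis of a
#' degenerate eigenspace).
#'
#' @param spec a [eigendecompose()] result.
#' @param value the eigenvalue to inspect.
#' @param nodes character vector of node labels.
#' @param value_tol absolute tolerance on the eigenvalue match.
#' @param support_tol singular values of the outside-rows block below this
#'   are treated as zero.
#' @return integer count.
#' @export
localized_eigencount <- function(spec, value, nodes, value_tol = 1e-8,
                                 support_tol = 1e-8) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  cols <- which(abs(spec$values - value) <= value_tol)
  if (length(cols) == 0L) return(0L)
  idx <- match(nodes, spec$labels)
  if (anyNA(idx)) stop("unknown node labels")
  outside <- setdiff(seq_along(spec$labels), idx)
  M <- spec$vectors[outside, cols, drop = FALSE]
  if (length(outside) == 0L) return(length(cols))
  sv <- svd(M, nu = 0, nv = 0)$d
  length(cols) - sum(sv > support_tol)
}

#' Randomly rotate the eigenbasis inside each degenerate block
#'
#' Replaces the eigenvector columns of every degenerate block by an
#' orthogonally rotated basis of the same eigenspace (seeded).  Detection at
#' block boundaries is basis-invariant, so [detect_transition()] output must
#' be unchanged under this operation; used as an invariance test utility.
#'
#' @param spec a [eigendecompose()] result.
#' @param seed RNG seed for the rotations.
#' @return a `laplacian_spectrum` with rotated eigenvectors.
#' @export
rotate_degenerate_basis <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  V <- spec$vectors
  with_seed(seed, {
    for (b in seq_len(nrow(spec$blocks))) {
      lo <- spec$blocks$lo[b]; hi <- spec$blocks$hi[b]
      k <- hi - lo + 1L
      if (k < 2L) next
      Q <- qr.Q(qr(matrix(stats::rnorm(k * k), k, k)))
      V[, lo:hi] <- V[, lo:hi, drop = FALSE] %*% Q
    }
  })
  spec$vectors <- V
  spec
}
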