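#' Construct a weighted graph from an adjacency matrix
#'
#' A `weighted_graph` is the basic container of the package: an undirected,
#' connected graph with nonnegative edge weights, stored as a dense symmetric
#' adjacency matrix with zero diagonal, plus the node labels of the input
#' file.  It is the source of the graph Laplacian on which every prediction
#' in this package is based.
#'
#' @param adjacency numeric N x N matrix, symmetric, nonnegative, zero
#'   diagonal.
#' @param labels optional character vector of node labels (defaults to
#'   `"1" ... "N"`).
#' @param tol relative tolerance for the symmetry check.
#' @return an object of class `weighted_graph` with elements `adjacency`
#'   (dense symmetric matrix with labels as dimnames) and `labels`.
#' @export
weighted_graph <- function(adjacency, labels = NULL, tol = 1e-12) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n < 2L || ncol(adjacency) != n) {
    stop("adjacency must be a square matrix with at least 2 nodes")
  }
  if (!is.numeric(adjacency) || anyNA(adjacency)) {
    stop("adjacency must be numeric without missing values")
  }
  scale <- max(abs(adjacency), 1)
  if (max(abs(adjacency - t(adjacency))) > tol * scale) {
    stop("adjacency matrix is not symmetric within tolerance")
  }
  adjacency <- (adjacency + t(adjacency)) / 2
  if (any(adjacency < 0)) stop("negative edge weight")
  if (any(diag(adjacency) != 0)) stop("self-loop: diagonal entries must be zero")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match matrix size")
  if (anyDuplicated(labels)) stop("duplicated node labels")
  dimnames(adjacency) <- list(labels, labels)
  g <- structure(list(adjacency = adjacency, labels = labels),
                 class = "weighted_graph")
  if (!is_connected_graph(g)) stop("disconnected graph: lambda_2 = 0 makes every predicted threshold infinite")
  g
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- length(x$labels)
  m <- sum(x$adjacency > 0) / 2
  cat(sprintf("weighted_graph: %d nodes, %d edges, total strength %.4g\n",
              n, m, sum(x$adjacency) / 2))
  invisible(x)
}

n_nodes <- function(g) length(g$labels)

is_connected_graph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  igraph::is_connected(ig)
}

#' Read a graph from a file
#'
#' Supported dialects: whitespace-separated edge list (`u v w`, weight
#' optional with default 1, `#` comments, each undirected edge stated once or
#' twice), Matrix Market coordinate symmetric adjacency, and GraphML with an
#' optional `weight` edge attribute.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"matrix-market"`, `"graphml"`.
#' @return a [weighted_graph()].
#' @export
read_graph <- function(path, format = c("edgelist", "matrix-market", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  switch(format,
    "edgelist" = read_edgelist(path),
    "matrix-market" = read_mm_adjacency(path),
    "graphml" = read_graphml(path)
  )
}

read_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty edge list")
  parts <- strsplit(lines, "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L)) stop("malformed edge list: expected 'u v [w]' per line")
  u <- vapply(parts, `[[`, "", 1L)
  v <- vapply(parts, `[[`, "", 2L)
  w <- vapply(parts, function(p) {
    if (length(p) == 3L) {
      x <- suppressWarnings(as.numeric(p[[3L]]))
      if (is.na(x)) stop("malformed edge weight: ", p[[3L]])
      x
    } else 1.0
  }, 0.0)
  if (any(u == v)) stop("self-loop in edge list")
  labels <- unique(c(rbind(u, v)))
  n <- length(labels)
  if (n < 2L) stop("graph must have at least 2 nodes")
  iu <- match(u, labels); iv <- match(v, labels)
  A <- matrix(0, n, n)
  seen <- new.env(parent = emptyenv())
  for (k in seq_along(iu)) {
    i <- min(iu[k], iv[k]); j <- max(iu[k], iv[k])
    key <- paste0(i, "_", j)
    prev <- seen[[key]]
    if (!is.null(prev)) {
      if (prev != w[k]) {
        stop(sprintf("conflicting duplicate edge %s-%s: weights %g and %g",
                     u[k], v[k], prev, w[k]))
      }
    } else {
      seen[[key]] <- w[k]
    }
    A[i, j] <- w[k]; A[j, i] <- w[k]
  }
  weighted_graph(A, labels)
}

read_mm_adjacency <- function(path) {
  M <- tryCatch(Matrix::readMM(path), error = function(e) {
    stop("malformed Matrix Market file: ", conditionMessage(e))
  })
  if (nrow(M) != ncol(M)) stop("adjacency must be square")
  # symmetric coordinate files store one triangle; as.matrix() expands it.
  # General files must state both triangles (validated by weighted_graph).
  A <- as.matrix(M)
  if (is.logical(A)) A[] <- as.numeric(A)   # pattern (binary) files
  weighted_graph(A)
}

read_graphml <- function(path) {
  ig <- tryCatch(igraph::read_graph(path, format = "graphml"),
                 error = function(e) stop("malformed GraphML: ", conditionMessage(e)))
  if (!("weight" %in% igraph::edge_attr_names(ig))) {
    igraph::E(ig)$weight <- 1.0
  }
  labels <- if ("name" %in% igraph::vertex_attr_names(ig)) {
    igraph::V(ig)$name
  } else {
    as.character(seq_len(igraph::vcount(ig)))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(ig, attr = "weight", sparse = TRUE))
  weighted_graph(A, labels)
}

#' Write a graph to a file
#'
#' The written file round-trips through [read_graph()]: labels and weights
#' are reproduced exactly, though node order may differ (edge lists list
#' nodes in order of first appearance; Matrix Market drops labels and
#' renumbers nodes `1..N` in the order of the input labels).
#'
#' @param g a [weighted_graph()].
#' @param path output path.
#' @param format one of `"edgelist"`, `"matrix-market"`, `"graphml"`.
#' @export
write_graph <- function(g, path, format = c("edgelist", "matrix-market", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(g, "weighted_graph"))
  switch(format,
    "edgelist" = {
      idx <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
      lines <- sprintf("%s\t%s\t%.17g",
                       g$labels[idx[, 1L]], g$labels[idx[, 2L]],
                       g$adjacency[idx])
      writeLines(c("# u v w (undirected)", lines), path)
    },
    "matrix-market" = {
      # multiply by 1.0: keeps a numeric (not pattern) sparse matrix so
      # unit weights round-trip as numbers
      M <- Matrix::Matrix(g$adjacency, sparse = TRUE) * 1.0
      Matrix::writeMM(M, path)
    },
    "graphml" = {
      ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
      igraph::V(ig)$name <- g$labels
      igraph::write_graph(ig, path, format = "graphml")
    }
  )
  invisible(path)
}

#' Graph Laplacian
#'
#' Returns `L = D - A` where `D` is the diagonal matrix of node strengths
#' (row sums of the adjacency).  Rows of `L` sum to zero, which guarantees
#' the existence and invariance of the fully synchronized solution of the
#' coupled network.
#'
#' @param g a [weighted_graph()].
#' @return symmetric N x N matrix with zero row sums.
#' @export
laplacian_of <- function(g) {
  stopifnot(inherits(g, "weighted_graph"))
  A <- g$adjacency
  L <- diag(rowSums(A)) - A
  dimnames(L) <- dimnames(A)
  L
}

#' Full Laplacian eigendecomposition with degeneracy grouping
#'
#' Computes the ordered eigenvalues `0 = lambda_1 < lambda_2 <= ... <=
#' lambda_N` and an orthonormal eigenvector matrix `V` (columns are
#' eigenvectors), and chains consecutive eigenvalues into degenerate blocks:
#' two consecutive eigenvalues belong to the same block iff their gap is at
#' most `grouping_tol * max(1, lambda)`.  Degenerate blocks are where
#' localized spectral structure (and hence cluster synchronization) lives.
#'
#' @param g a [weighted_graph()].
#' @param grouping_tol relative degeneracy-grouping tolerance.
#' @return an object of class `laplacian_spectrum` with elements `values`,
#'   `vectors`, `blocks` (data.frame with columns `lo`, `hi`, `value`),
#'   and `labels`.
#' @export
eigendecompose <- function(g, grouping_tol = 1e-8) {
  stopifnot(inherits(g, "weighted_graph"))
  n <- n_nodes(g)
  if (n > 20000L) {
    stop("graph too large for a full dense eigendecomposition (N > 20000); ",
         "the method needs the complete spectrum")
  }
  L <- laplacian_of(g)
  e <- eigen(L, symmetric = TRUE)
  ord <- rev(seq_len(n))           # eigen() returns decreasing order
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  values[1L] <- 0                  # exact by construction of L
  # fix the sign convention of the constant eigenvector
  if (vectors[1L, 1L] < 0) vectors[, 1L] <- -vectors[, 1L]
  blocks <- group_eigen_blocks(values, grouping_tol)
  structure(list(values = values, vectors = vectors, blocks = blocks,
                 labels = g$labels, grouping_tol = grouping_tol),
            class = "laplacian_spectrum")
}

# Chain consecutive eigenvalues into maximal degenerate blocks.
group_eigen_blocks <- function(values, grouping_tol) {
  n <- length(values)
  gaps <- diff(values)
  new_block <- gaps > grouping_tol * pmax(1, values[-1L])
  ids <- cumsum(c(TRUE, new_block))
  lo <- match(unique(ids), ids)
  hi <- c(lo[-1L] - 1L, n)
  data.frame(lo = lo, hi = hi,
             value = vapply(seq_along(lo),
                            function(b) mean(values[lo[b]:hi[b]]), 0.0))
}

#' @export
print.laplacian_spectrum <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("laplacian_spectrum: N = %d, lambda_2 = %.6g, lambda_N = %.6g\n",
              n, x$values[2L], x$values[n]))
  ndeg <- sum(x$blocks$hi - x$blocks$lo + 1L > 1L)
  cat(sprintf("  %d blocks (%d degenerate)\n", nrow(x$blocks), ndeg))
  invisible(x)
}
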