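#' Squared eigenvector-difference matrix E
#'
#' For eigenvector `v_i`, entry `(j,k)` is `(v_ij - v_ik)^2`.  These matrices
#' accumulate into the `S_n` matrices whose entries equal to 2 flag node
#' pairs that agree on every eigenvector below level `n`, i.e. pairs that can
#' synchronize once all levels from `n` upward are stable.
#'
#' @param spec a [eigendecompose()] result.
#' @param i eigen index, `1 <= i <= N`.
#' @return symmetric N x N matrix with zero diagonal, entries in `[0, 2]`.
#' @export
e_matrix <- function(spec, i) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  n <- length(spec$values)
  if (!(is.numeric(i) && length(i) == 1L && i >= 1 && i <= n)) {
    stop("eigen index out of range")
  }
  v <- spec$vectors[, as.integer(i)]
  outer(v, v, FUN = function(a, b) (a - b)^2)
}

#' Cumulative spectral distance matrix S_n
#'
#' `S_n = sum_{k >= n} E_{lambda_k}`, computed directly from the eigenvector
#' matrix.  Off-diagonal entries are squared norms of differences of rows of
#' the eigenvector matrix truncated to their last `N - n + 1` components,
#' hence bounded by 2, with equality iff the two nodes have identical
#' components on every eigenvector below level `n`.
#'
#' @param spec a [eigendecompose()] result.
#' @param n eigen index, `1 <= n <= N`.
#' @return symmetric N x N matrix, zero diagonal, entries in `[0, 2]`.
#' @export
s_matrix_at <- function(spec, n) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  N <- length(spec$values)
  if (!(is.numeric(n) && length(n) == 1L && n >= 1 && n <= N)) {
    stop("eigen index out of range")
  }
  W <- spec$vectors[, as.integer(n):N, drop = FALSE]
  r <- rowSums(W^2)
  S <- outer(r, r, `+`) - 2 * tcrossprod(W)
  S[S < 0] <- 0
  diag(S) <- 0
  S
}

#' Predict the sequence of cluster-synchronization events
#'
#' The core prediction: inspect the `S_n` matrices at degenerate-block
#' boundaries in decreasing eigenvalue order and look for entries equal to 2.
#' Each hit defines a cluster that synchronizes at relative coupling
#' `1/lambda_p` (in units of the critical parameter nu* of the node
#' dynamics).  Events are classified as `formation` (all members new),
#' `growth` (an existing cluster absorbs new nodes), `merge` (two or more
#' existing clusters unite), or `complete` (the final all-node event at
#' `lambda_2`).
#'
#' Internally the equivalent cumulative criterion is used: an off-diagonal
#' entry of `S_n` equals 2 exactly when the accumulated squared eigenvector
#' differences over all levels below `n` vanish, so blocks are processed in
#' increasing eigenvalue order while pruning separated pairs; the emitted
#' ordering is the paper-facing decreasing inspection.
#'
#' @param spec a [eigendecompose()] result from a connected graph.
#' @param entry_tol tolerance for `|S - 2| <= entry_tol` detection, applied
#'   to the accumulated squared differences.  The default is deliberately
#'   close to machine precision: entries of genuine cells differ from 2 by
#'   pure rounding noise (~1e-25), while accidental near-agreements of
#'   unequal eigenvector components stay many orders of magnitude above it.
#' @return an object of class `transition_plan`; see [scale_plan()] to attach
#'   absolute couplings.
#' @export
detect_transition <- function(spec, entry_tol = 1e-20) {
  stopifnot(inherits(spec, "laplacian_spectrum"))
  N <- length(spec$values)
  blocks <- spec$blocks
  # candidate node pairs (i < j) still agreeing on all processed levels
  pi_ <- rep.int(seq_len(N - 1L), times = (N - 1L):1L)
  pj_ <- sequence((N - 1L):1L, from = 2:N)
  D <- numeric(length(pi_))
  assigned_block <- integer(length(pi_))  # 0 = not yet separated
  alive <- seq_along(pi_)
  for (b in seq_len(nrow(blocks))[-1L]) {  # skip the lambda_1 = 0 block
    if (length(alive) == 0L) break
    cols <- blocks$lo[b]:blocks$hi[b]
    d_add <- numeric(length(alive))
    for (k in cols) {
      v <- spec$vectors[, k]
      d_add <- d_add + (v[pi_[alive]] - v[pj_[alive]])^2
    }
    Dnew <- D[alive] + d_add
    sep <- Dnew > entry_tol
    assigned_block[alive[sep]] <- b
    D[alive] <- Dnew
    alive <- alive[!sep]
  }
  if (length(alive) > 0L) {
    # numerically identical rows of V cannot occur for an orthogonal V
    stop("internal error: node pairs never separated by any eigenvector")
  }
  build_events(spec, pi_, pj_, assigned_block, entry_tol)
}

# Assemble ordered events from per-pair first-separating blocks.
build_events <- function(spec, pi_, pj_, assigned_block, entry_tol) {
  N <- length(spec$values)
  blocks <- spec$blocks
  labels <- spec$labels
  parent <- seq_len(N)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  events <- list()
  cluster_of <- rep(0L, N)      # id of current non-singleton cluster
  next_cluster_id <- 1L
  cluster_nodes <- list()
  for (b in rev(seq_len(nrow(blocks))[-1L])) {
    sel <- assigned_block == b
    if (!any(sel)) next
    ii <- pi_[sel]; jj <- pj_[sel]
    # transitivity check: the "entry = 2" relation must be an equivalence
    touched <- unique(c(ii, jj))
    for (k in seq_along(ii)) {
      ri <- find(ii[k]); rj <- find(jj[k])
      if (ri != rj) parent[ri] <- rj
    }
    roots <- vapply(touched, find, 0L)
    changed_roots <- unique(roots)
    lam <- blocks$value[b]
    is_final <- b == 2L
    block_events <- list()
    for (r in changed_roots) {
      members <- touched[roots == r]
      # absorb full membership of prior clusters that share a node
      prior_ids <- unique(cluster_of[members])
      prior_ids <- prior_ids[prior_ids != 0L]
      nodes <- sort(unique(c(members, unlist(cluster_nodes[prior_ids]))))
      verify_pair_closure(spec, nodes, b, entry_tol)
      new_nodes <- nodes[cluster_of[nodes] == 0L]
      type <- if (is_final && length(nodes) == N) "complete"
      else if (length(prior_ids) == 0L) "formation"
      else if (length(prior_ids) == 1L) "growth"
      else "merge"
      ev <- list(nodes = labels[nodes],
                 block_eigenvalue = lam,
                 relative_coupling = 1 / lam,
                 absolute_coupling = NA_real_,
                 event_type = type,
                 merged_from = lapply(prior_ids, function(id) labels[cluster_nodes[[id]]]),
                 reachable = TRUE)
      block_events[[length(block_events) + 1L]] <- ev
      id <- next_cluster_id
      next_cluster_id <- next_cluster_id + 1L
      cluster_nodes[[id]] <- nodes
      cluster_of[nodes] <- id
    }
    # deterministic ordering of simultaneous events: by smallest node index
    ord <- order(vapply(block_events,
                        function(e) match(e$nodes[1L], labels), 0L))
    events <- c(events, block_events[ord])
  }
  structure(list(events = events, class_info = NULL, labels = labels,
                 entry_tol = entry_tol),
            class = "transition_plan")
}

# Abort with a diagnostic if the pair relation at a block boundary is not
# transitive at the working tolerance (all within-cluster accumulated
# distances must vanish).
verify_pair_closure <- function(spec, nodes, b, entry_tol) {
  if (length(nodes) < 3L) return(invisible(TRUE))
  lo <- spec$blocks$lo[b]
  W <- spec$vectors[nodes, seq_len(lo - 1L), drop = FALSE]
  # direct differencing: the Gram-matrix form of this quantity cancels
  # catastrophically near zero, which is exactly where it is evaluated
  k <- length(nodes)
  dmax <- 0
  for (a in seq_len(k - 1L)) {
    d <- rowSums((W[rep(a, k - a), , drop = FALSE] -
                  W[(a + 1L):k, , drop = FALSE])^2)
    dmax <- max(dmax, d)
  }
  if (dmax > 10 * entry_tol) {
    stop(sprintf(paste0("entry-equals-2 relation is not transitive at block %d ",
                        "(max within-cluster deviation %.3g); ",
                        "adjust entry_tol or grouping_tol"),
                 b, dmax))
  }
  invisible(TRUE)
}

#' @export
print.transition_plan <- function(x, ...) {
  cat(sprintf("transition_plan: %d events\n", length(x$events)))
  for (ev in x$events) {
    nodes <- if (length(ev$nodes) > 8L) {
      paste0(paste(utils::head(ev$nodes, 8L), collapse = ","), ",... (",
             length(ev$nodes), " nodes)")
    } else paste(ev$nodes, collapse = ",")
    cat(sprintf("  %-9s lambda = %-8.5g rel. d = %-8.5g%s {%s}%s\n",
                ev$event_type, ev$block_eigenvalue, ev$relative_coupling,
                if (is.na(ev$absolute_coupling)) ""
                else sprintf(" d = %-8.5g", ev$absolute_coupling),
                nodes,
                if (isTRUE(ev$reachable)) "" else " [unreachable]"))
  }
  invisible(x)
}

#' Attach absolute coupling strengths to a transition plan
#'
#' Multiplies each event's relative coupling `1/lambda_p` by the critical
#' parameter of the node dynamics: `nu*` for Class II systems, `nu1*` for
#' Class III.  For Class III the upper stability bound `d_max = nu2* /
#' lambda_N` is enforced: events predicted beyond it are flagged
#' unreachable.
#'
#' @param plan a [detect_transition()] result.
#' @param msf a [classify_msf()] result, or a single positive number taken as
#'   a literal Class II `nu*`.
#' @param lambda_N largest Laplacian eigenvalue; only needed for the Class
#'   III bound when `msf` is a classification (taken from it otherwise
#'   ignored).
#' @return the plan with `absolute_coupling` filled in and `reachable` flags
#'   set; `class_info` carries the classification used.
#' @export
scale_plan <- function(plan, msf, lambda_N = NULL) {
  stopifnot(inherits(plan, "transition_plan"))
  if (is.numeric(msf) && length(msf) == 1L) {
    if (!is.finite(msf) || msf <= 0) {
      stop("nu* must be finite and positive (a periodic unit has nu* = 0 and ",
           "synchronizes at infinitesimal coupling)")
    }
    nu1 <- msf; nu2 <- Inf
    plan$class_info <- list(class_label = "II", nu_star = msf)
  } else {
    stopifnot(inherits(msf, "msf_classification"))
    if (msf$class_label == "I") {
      stop("Class I systems defy synchronization: no finite threshold exists")
    }
    nu1 <- if (msf$class_label == "II") msf$nu_star else msf$nu1_star
    nu2 <- if (msf$class_label == "III") msf$nu2_star else Inf
    if (!is.finite(nu1) || nu1 <= 0) stop("nu* must be finite and positive")
    plan$class_info <- msf
  }
  lamN <- if (!is.null(lambda_N)) lambda_N else {
    max(vapply(plan$events, `[[`, 0.0, "block_eigenvalue"))
  }
  d_max <- nu2 / lamN
  plan$events <- lapply(plan$events, function(ev) {
    ev$absolute_coupling <- nu1 * ev$relative_coupling
    ev$reachable <- ev$absolute_coupling < d_max
    ev
  })
  plan
}

#' External equitable cell partition of a graph
#'
#' Finds the partition of nodes into cells such that all members of a cell
#' have identical connections (with identical weights) to every node outside
#' the cell, i.e. they receive the same input from the rest of the network.
#' These cells are exactly the node sets that can emerge as synchronized
#' clusters during the transition.  The initial pairwise relation (rows of
#' the Laplacian agreeing outside the pair) is refined by splitting on
#' external-row signatures until every candidate cell satisfies the cell
#' condition.
#'
#' @param g a [weighted_graph()].
#' @param weight_tol absolute tolerance for weight comparisons.
#' @return an object of class `cell_partition`: a list with `cells` (list of
#'   character vectors of node labels, singletons included).
#' @export
equitable_cells <- function(g, weight_tol = 1e-9) {
  stopifnot(inherits(g, "weighted_graph"))
  L <- laplacian_of(g)
  n <- nrow(L)
  # candidate pairs must have equal strength (diagonal) and equal mutual rows
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  deg <- diag(L)
  ord <- order(deg)
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    for (b in (a + 1L):n) {
      j <- ord[b]
      if (deg[j] - deg[i] > weight_tol) break
      keep <- setdiff(seq_len(n), c(i, j))
      if (all(abs(L[i, keep] - L[j, keep]) <= weight_tol)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  cells <- split(seq_len(n), vapply(seq_len(n), find, 0L))
  # refinement: split any candidate cell violating the cell condition on the
  # external-row signature, until a fixed point (at most n iterations)
  repeat {
    changed <- FALSE
    new_cells <- list()
    for (cell in cells) {
      if (length(cell) < 2L) { new_cells <- c(new_cells, list(cell)); next }
      outside <- setdiff(seq_len(n), cell)
      rows <- L[cell, outside, drop = FALSE]
      key <- apply(rows, 1L, function(r) paste(round(r / weight_tol), collapse = ","))
      parts <- split(cell, key)
      if (length(parts) > 1L) changed <- TRUE
      new_cells <- c(new_cells, unname(parts))
    }
    cells <- new_cells
    if (!changed) break
  }
  cells <- lapply(cells, function(cell) g$labels[sort(cell)])
  cells <- cells[order(vapply(cells, function(x) match(x[1L], g$labels), 0L))]
  structure(list(cells = cells, labels = g$labels), class = "cell_partition")
}

#' @export
print.cell_partition <- function(x, ...) {
  nt <- sum(lengths(x$cells) > 1L)
  cat(sprintf("cell_partition: %d cells (%d non-trivial)\n",
              length(x$cells), nt))
  for (cell in x$cells) {
    if (length(cell) > 1L) cat("  {", paste(cell, collapse = ","), "}\n")
  }
  invisible(x)
}

#' Cross-check a transition plan against the equitable-cell condition
#'
#' Every non-complete event predicted from the spectrum must name a node set
#' whose members have identical connections (with identical weights) to all
#' outside nodes.  Violations indicate tolerance trouble in the
#' eigendecomposition or detection, and are reported rather than silently
#' trusted.
#'
#' @param plan a [detect_transition()] result produced from `g`'s spectrum.
#' @param g the originating [weighted_graph()].
#' @param weight_tol absolute tolerance for weight comparisons.
#' @return a list with `ok` (logical) and `violations` (list of event node
#'   sets that fail, each with the maximum row deviation observed).
#' @export
verify_plan <- function(plan, g, weight_tol = 1e-9) {
  stopifnot(inherits(plan, "transition_plan"), inherits(g, "weighted_graph"))
  L <- laplacian_of(g)
  violations <- list()
  for (ev in plan$events) {
    if (ev$event_type == "complete") next
    idx <- match(ev$nodes, g$labels)
    if (anyNA(idx)) {
      violations[[length(violations) + 1L]] <-
        list(nodes = ev$nodes, max_deviation = Inf, reason = "unknown labels")
      next
    }
    outside <- setdiff(seq_len(nrow(L)), idx)
    if (length(outside) == 0L) next
    rows <- L[idx, outside, drop = FALSE]
    dev <- max(apply(rows, 2L, function(col) diff(range(col))))
    if (dev > weight_tol) {
      violations[[length(violations) + 1L]] <-
        list(nodes = ev$nodes, max_deviation = dev)
    }
  }
  list(ok = length(violations) == 0L, violations = violations)
}

#' Serialize a transition plan to JSON
#'
#' @param plan a [detect_transition()] (optionally [scale_plan()]ed) result.
#' @param path optional output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "transition_plan"))
  obj <- list(
    schema_version = 1L,
    events = lapply(plan$events, function(ev) {
      list(nodes = as.list(ev$nodes),
           block_eigenvalue = ev$block_eigenvalue,
           relative_coupling = ev$relative_coupling,
           absolute_coupling = if (is.na(ev$absolute_coupling)) NULL
                               else ev$absolute_coupling,
           event_type = ev$event_type,
           merged_from = lapply(ev$merged_from, as.list),
           reachable = ev$reachable)
    })
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
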