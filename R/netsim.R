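#' Simulation configuration
#'
#' @param total_time total simulated time units.
#' @param error_window length of the final window over which synchronization
#'   errors are averaged.
#' @param rtol,atol integrator tolerances.
#' @param store_dt sampling interval of the stored trajectory.
#' @param seed seed controlling the initial conditions (and heterogeneity
#'   draws when applicable).
#' @param ic_amplitude amplitude of the per-node uniform jitter around the
#'   system's default initial state.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(total_time = 1500, error_window = 100,
                       rtol = 1e-6, atol = 1e-6, store_dt = 0.1,
                       seed = 1L, ic_amplitude = 1) {
  stopifnot(total_time > error_window, error_window > 0, store_dt > 0)
  structure(list(total_time = total_time, error_window = error_window,
                 rtol = rtol, atol = atol, store_dt = store_dt,
                 seed = as.integer(seed), ic_amplitude = ic_amplitude),
            class = "sim_config")
}

#' Heterogeneous node parameters
#'
#' Describes node-to-node parameter scatter: parameter `parameter` of each
#' node is drawn independently and uniformly from
#' `[value - epsilon, value + epsilon]` around the system default.  With
#' heterogeneous units the exact synchronous solution ceases to exist, but
#' the predicted cluster sequence is still observed for small `epsilon`.
#'
#' @param parameter name of the system parameter to scatter (e.g. `"b"` for
#'   the Roessler system).
#' @param epsilon half-width of the uniform distribution (>= 0).
#' @param seed seed for the draws.
#' @return an object of class `heterogeneity_spec`.
#' @export
heterogeneity_spec <- function(parameter, epsilon, seed = 1L) {
  stopifnot(is.character(parameter), length(parameter) == 1L, epsilon >= 0)
  structure(list(parameter = parameter, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "heterogeneity_spec")
}

# Per-node 3 x N parameter matrix for the compiled network flow,
# applying a heterogeneity draw when given.  Returns list(P, draws).
node_params <- function(sys, n, het = NULL) {
  base <- unname(c(sys$params, numeric(3L)))[1:3]
  P <- matrix(base, nrow = 3L, ncol = n)
  draws <- NULL
  if (!is.null(het)) {
    k <- match(het$parameter, names(sys$params))
    if (is.na(k)) {
      stop("unknown heterogeneity parameter '", het$parameter,
           "' for system ", sys$name)
    }
    centre <- sys$params[[k]]
    draws <- with_seed(het$seed,
                       stats::runif(n, centre - het$epsilon,
                                    centre + het$epsilon))
    P[k, ] <- draws
  }
  list(P = P, draws = draws)
}

#' Integrate the coupled network
#'
#' Integrates `x_i' = f(x_i) - d * sum_j L_ij g(x_j)` for all nodes with a
#' compiled right-hand side, storing the state every `store_dt` time units.
#' Initial conditions are per-node uniform jitters of amplitude
#' `ic_amplitude` around the system's default state, controlled by the
#' config seed.
#'
#' @param g a [weighted_graph()].
#' @param sys a [dynamical_systems] object.
#' @param d coupling strength (>= 0).
#' @param cfg a [sim_config()].
#' @param het optional [heterogeneity_spec()].
#' @return an object of class `network_trajectory`: `times`, `states`
#'   (time x (N*m) matrix, node-major columns), `labels`, `sys`, `d`,
#'   `cfg`, and `het_draws` (per-node parameter values or `NULL`).
#' @export
simulate_network <- function(g, sys, d, cfg = sim_config(), het = NULL) {
  stopifnot(inherits(g, "weighted_graph"), inherits(sys, "dynamical_system"),
            inherits(cfg, "sim_config"), is.numeric(d), length(d) == 1L,
            d >= 0)
  n <- n_nodes(g)
  if (n > 512L) {
    stop("network too large for the dense compiled simulator (N > 512)")
  }
  m <- sys$dimension
  L <- laplacian_of(g)
  np <- node_params(sys, n, het)
  y0 <- with_seed(cfg$seed, {
    jit <- stats::runif(n * m, -cfg$ic_amplitude, cfg$ic_amplitude)
    rep(sys$default_initial_state, n) + jit
  })
  .Call(C_net_setup, sys$sysid, as.numeric(d), as.numeric(L), np$P)
  times <- seq(0, cfg$total_time, by = cfg$store_dt)
  out <- deSolve::ode(y = y0, times = times, func = "derivs_net",
                      parms = NULL, dllname = "syncpath", initfunc = NULL,
                      method = "lsoda", rtol = cfg$rtol, atol = cfg$atol,
                      maxsteps = 50000)
  if (nrow(out) < length(times) || any(!is.finite(out[nrow(out), ]))) {
    stop(sprintf("integration blew up at coupling d = %g", d))
  }
  structure(list(times = out[, 1L], states = out[, -1L, drop = FALSE],
                 labels = g$labels, sys = sys, d = d, cfg = cfg,
                 het_draws = np$draws),
            class = "network_trajectory")
}

#' Cluster synchronization error
#'
#' Time-average, over the final `window` of the trajectory, of the RMS
#' deviation of the cluster members from the instantaneous cluster mean:
#' `E_cl = < sqrt(mean_i |x_i - xbar_cl|^2) >_window`.  By default only the
#' coupled component of the state enters the norm (the error vanishes there
#' iff it vanishes for the full state on a synchronized cluster);
#' `variables` selects any other component set.
#'
#' @param traj a [simulate_network()] result.
#' @param nodes character vector of node labels (>= 2) forming the cluster.
#' @param window averaging window (defaults to the config's
#'   `error_window`).
#' @param variables integer vector of state-component indices to track
#'   (default: the coupled component).
#' @return the scalar error.
#' @export
cluster_error <- function(traj, nodes, window = NULL, variables = NULL) {
  stopifnot(inherits(traj, "network_trajectory"))
  if (length(nodes) < 2L) stop("a cluster needs at least 2 nodes")
  idx <- match(nodes, traj$labels)
  if (anyNA(idx)) stop("unknown node labels")
  m <- traj$sys$dimension
  if (is.null(variables)) variables <- traj$sys$coupled_component
  variables <- as.integer(variables)
  if (length(variables) == 0L) stop("empty variable set")
  stopifnot(all(variables >= 1L & variables <= m))
  if (is.null(window)) window <- traj$cfg$error_window
  tmax <- traj$times[length(traj$times)]
  sel <- traj$times >= tmax - window
  if (!any(sel)) stop("window outside trajectory span")
  sq <- 0
  for (v in variables) {
    X <- traj$states[sel, (idx - 1L) * m + v, drop = FALSE]
    dev <- X - rowMeans(X)
    sq <- sq + rowMeans(dev^2)
  }
  mean(sqrt(sq))
}

#' Synchronization-error curves over a coupling sweep
#'
#' For each coupling value in `d_grid` the network is integrated
#' `n_ensembles` times with seed-varied initial conditions (and, when
#' heterogeneity is given, seed-varied parameter draws); the cluster errors
#' are ensemble-averaged and each cluster's curve is normalized by its
#' maximum over the grid so that it ranges from 1 (incoherent) towards 0
#' (synchronized).  The entire network is always appended as a final
#' cluster named `"EN"`.
#'
#' @param g a [weighted_graph()].
#' @param sys a [dynamical_systems] object.
#' @param d_grid increasing vector of coupling strengths.
#' @param clusters named list of character vectors of node labels.
#' @param n_ensembles runs per coupling value.
#' @param cfg a [sim_config()]; its seed is the master seed of the sweep.
#' @param het optional [heterogeneity_spec()].
#' @return an object of class `sync_error_curves` with `d_grid`, `raw`
#'   and `normalized` (cluster x coupling matrices), `clusters`,
#'   `n_ensembles`, and `cfg`.
#' @export
sweep_errors <- function(g, sys, d_grid, clusters = list(),
                         n_ensembles = 10L, cfg = sim_config(), het = NULL) {
  stopifnot(is.numeric(d_grid), length(d_grid) >= 1L,
            !is.unsorted(d_grid, strictly = TRUE))
  if (is.null(names(clusters)) && length(clusters)) {
    names(clusters) <- paste0("C", seq_along(clusters))
  }
  clusters <- c(clusters, list(EN = g$labels))
  raw <- matrix(0, nrow = length(clusters), ncol = length(d_grid),
                dimnames = list(names(clusters), NULL))
  for (di in seq_along(d_grid)) {
    for (e in seq_len(n_ensembles)) {
      run_seed <- cfg$seed + 7919L * (e - 1L) + 104729L * (di - 1L)
      run_cfg <- cfg
      run_cfg$seed <- run_seed
      run_het <- het
      if (!is.null(het)) run_het$seed <- het$seed + run_seed
      traj <- simulate_network(g, sys, d_grid[di], run_cfg, run_het)
      for (ci in seq_along(clusters)) {
        raw[ci, di] <- raw[ci, di] + cluster_error(traj, clusters[[ci]])
      }
    }
  }
  raw <- raw / n_ensembles
  norm <- raw
  for (ci in seq_len(nrow(raw))) {
    mx <- max(raw[ci, ])
    if (mx > 0) norm[ci, ] <- raw[ci, ] / mx
  }
  structure(list(d_grid = d_grid, raw = raw, normalized = norm,
                 clusters = clusters, n_ensembles = n_ensembles,
                 cfg = cfg, het = het,
                 normalization = "per-curve maximum over the sweep"),
            class = "sync_error_curves")
}

#' @export
print.sync_error_curves <- function(x, ...) {
  cat(sprintf("sync_error_curves: %d clusters x %d couplings (d in [%g, %g]), %d ensembles\n",
              nrow(x$raw), length(x$d_grid), min(x$d_grid), max(x$d_grid),
              x$n_ensembles))
  invisible(x)
}

#' Export error curves as tidy CSV
#'
#' Columns: `cluster_id, d, raw_error, normalized_error, n_ensembles`.
#'
#' @param curves a [sweep_errors()] result.
#' @param path output file.
#' @export
curves_to_csv <- function(curves, path) {
  stopifnot(inherits(curves, "sync_error_curves"))
  df <- data.frame(
    cluster_id = rep(rownames(curves$raw), times = length(curves$d_grid)),
    d = rep(curves$d_grid, each = nrow(curves$raw)),
    raw_error = as.vector(curves$raw),
    normalized_error = as.vector(curves$normalized),
    n_ensembles = curves$n_ensembles)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Empirical synchronization thresholds from error curves
#'
#' The threshold of a cluster is the smallest grid coupling at which its
#' normalized error falls below `eps_sync` and stays below for all larger
#' grid couplings; `NA` means not synchronized in the swept range.
#'
#' @param curves a [sweep_errors()] result.
#' @param eps_sync threshold on the normalized error, in (0, 1).
#' @return named numeric vector of thresholds (one per cluster, `NA` when
#'   absent).
#' @export
empirical_thresholds <- function(curves, eps_sync = 0.01) {
  stopifnot(inherits(curves, "sync_error_curves"),
            eps_sync > 0, eps_sync < 1)
  apply_names <- rownames(curves$normalized)
  res <- vapply(seq_len(nrow(curves$normalized)), function(ci) {
    below <- curves$normalized[ci, ] < eps_sync
    stays <- rev(cumprod(rev(below))) > 0   # below from here onward
    i <- which(stays)[1L]
    if (is.na(i)) NA_real_ else curves$d_grid[i]
  }, 0.0)
  names(res) <- apply_names
  res
}
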