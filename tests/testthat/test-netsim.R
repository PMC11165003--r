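# minimal hand-built trajectory for the error oracle
fake_trajectory <- function(states, labels, sys, times = NULL) {
  if (is.null(times)) times <- seq_len(nrow(states)) - 1
  structure(list(times = times, states = states, labels = labels,
                 sys = sys, d = 0,
                 cfg = sim_config(total_time = max(times) + 1,
                                  error_window = max(times) + 0.5),
                 het_draws = NULL),
            class = "network_trajectory")
}

test_that("cluster error matches closed-form cases", {
  sys <- linear_system()
  # identical trajectories: zero error
  X <- matrix(rep(sin(seq(0, 5, 0.5)), 3), ncol = 3)
  tr <- fake_trajectory(X, c("a", "b", "c"), sys)
  expect_equal(cluster_error(tr, c("a", "b", "c"), window = 5), 0)
  # two constant states 0 and 2c: mean c, both deviations c, RMS c
  cc <- 1.7
  X2 <- cbind(rep(0, 11), rep(2 * cc, 11))
  tr2 <- fake_trajectory(X2, c("a", "b"), sys)
  expect_equal(cluster_error(tr2, c("a", "b"), window = 5), cc)
  # contracts
  expect_error(cluster_error(tr, "a"), "at least 2")
  expect_error(cluster_error(tr, c("a", "zz")), "unknown node")
  expect_error(cluster_error(tr, c("a", "b"), variables = integer(0)),
               "empty variable")
})

test_that("identical initial conditions stay on the synchronization manifold", {
  g <- f4_graph()
  tr <- simulate_network(g, rossler_system(), 0.05,
                         sim_config(total_time = 60, error_window = 20,
                                    seed = 3, ic_amplitude = 0))
  expect_lt(cluster_error(tr, g$labels), 1e-8)
  # zero error in full-state mode as well
  expect_lt(cluster_error(tr, g$labels, variables = 1:3), 1e-8)
})

test_that("uncoupled nodes follow the isolated flow", {
  g <- f4_graph()
  cfg <- sim_config(total_time = 12, error_window = 4, store_dt = 0.2,
                    seed = 7, rtol = 1e-9, atol = 1e-9)
  tr <- simulate_network(g, rossler_system(), 0, cfg)
  # re-integrate node 2 alone from its own initial condition
  y0 <- tr$states[1, 4:6]
  iso <- deSolve::ode(y = c(y0, 0, 0, 0, 0), times = seq(0, 12, 0.2),
                      func = "derivs_rossler_var",
                      parms = c(0, 0.1, 0.1, 18), dllname = "syncpath",
                      initfunc = "initmod_var", method = "lsoda",
                      rtol = 1e-9, atol = 1e-9)
  expect_lt(max(abs(tr$states[, 4:6] - iso[, 2:4])), 1e-4)
})

test_that("above the predicted threshold the whole network synchronizes", {
  g <- f4_graph()
  nu_star <- 0.165   # Roessler y-coupling intercept computed by this package
  tr <- simulate_network(g, rossler_system(), 2 * nu_star / 2,
                         sim_config(seed = 11))
  en <- cluster_error(tr, g$labels)
  expect_lt(en / 3, 0.05)   # raw error, conservative scale bound
  expect_lt(en, 0.05)
})

test_that("heterogeneous parameters are drawn inside the stated interval", {
  g <- f4_graph()
  het <- heterogeneity_spec("b", 0.01, seed = 5)
  tr <- simulate_network(g, rossler_system(), 0.05,
                         sim_config(total_time = 30, error_window = 10,
                                    seed = 1), het)
  expect_equal(length(tr$het_draws), 4L)
  expect_true(all(tr$het_draws >= 0.09 & tr$het_draws <= 0.11))
  expect_error(simulate_network(g, rossler_system(), 0.05,
                                sim_config(total_time = 30,
                                           error_window = 10),
                                heterogeneity_spec("zeta", 0.01)),
               "unknown heterogeneity parameter")
})

test_that("with small heterogeneity errors stay positive but ordering holds", {
  g <- f4_graph()
  het <- heterogeneity_spec("b", 0.01, seed = 2)
  grid <- c(0.03, 0.06, 0.12)
  cur <- sweep_errors(g, rossler_system(), grid, list(C1 = c("3", "4")),
                      n_ensembles = 3, cfg = sim_config(seed = 8), het = het)
  # the exact synchronous solution ceases to exist: raw errors never vanish
  expect_true(all(cur$raw > 0))
  # but the cluster still orders before the entire network
  expect_lte(cur$normalized["C1", 2], cur$normalized["EN", 2])
})

test_that("sweeps are reproducible and normalized to peak 1", {
  g <- f4_graph()
  grid <- c(0.02, 0.08)
  cfg <- sim_config(total_time = 120, error_window = 40, seed = 21)
  c1 <- sweep_errors(g, rossler_system(), grid, list(C1 = c("3", "4")),
                     n_ensembles = 1, cfg = cfg)
  c2 <- sweep_errors(g, rossler_system(), grid, list(C1 = c("3", "4")),
                     n_ensembles = 1, cfg = cfg)
  expect_identical(c1$raw, c2$raw)   # bitwise determinism at fixed seed
  expect_true(all(abs(apply(c1$normalized, 1, max) - 1) < 1e-12))
  expect_true(all(c1$normalized >= 0 & c1$normalized <= 1))
})

test_that("converged errors are insensitive to doubling the run length", {
  g <- f4_graph()
  t1 <- simulate_network(g, rossler_system(), 0.02,
                         sim_config(total_time = 750, seed = 9))
  t2 <- simulate_network(g, rossler_system(), 0.02,
                         sim_config(total_time = 1500, seed = 9))
  e1 <- cluster_error(t1, g$labels)
  e2 <- cluster_error(t2, g$labels)
  expect_lt(abs(e1 - e2) / e2, 0.10)
})

test_that("threshold extraction follows the stays-below rule", {
  fake <- structure(list(
    d_grid = c(0.01, 0.02, 0.03, 0.04),
    raw = rbind(A = c(1, 1, 0.004, 0.002)),
    normalized = rbind(A = c(1, 1, 0.004, 0.002)),
    clusters = list(A = c("1", "2")), n_ensembles = 1,
    cfg = sim_config(), het = NULL, normalization = "max"),
    class = "sync_error_curves")
  expect_equal(unname(empirical_thresholds(fake, 0.01)["A"]), 0.03)
  # all-ones curve: not synchronized in range
  fake$normalized <- rbind(A = c(1, 1, 1, 1))
  expect_true(is.na(empirical_thresholds(fake, 0.01)["A"]))
  # a dip that does not stay below eps is not a threshold
  fake$normalized <- rbind(A = c(1, 0.005, 1, 0.002))
  expect_equal(unname(empirical_thresholds(fake, 0.01)["A"]), 0.04)
})

test_that("error curves export as tidy CSV", {
  g <- f4_graph()
  cur <- sweep_errors(g, rossler_system(), c(0.02, 0.1),
                      list(C1 = c("3", "4")), n_ensembles = 1,
                      cfg = sim_config(total_time = 120, error_window = 40,
                                       seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  curves_to_csv(cur, path)
  df <- utils::read.csv(path)
  expect_equal(names(df), c("cluster_id", "d", "raw_error",
                            "normalized_error", "n_ensembles"))
  expect_equal(nrow(df), 4L)
  expect_setequal(unique(df$cluster_id), c("C1", "EN"))
})
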