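# brute-force oracle: entry (j,k) of E_{lambda_i} by a direct double loop
e_matrix_oracle <- function(V, i) {
  n <- nrow(V)
  E <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) E[j, k] <- (V[j, i] - V[k, i])^2
  }
  E
}

test_that("E matrices match the squared-difference definition", {
  sp <- eigendecompose(f4_graph())
  # constant eigenvector: E is identically zero
  expect_equal(e_matrix(sp, 1), matrix(0, 4, 4), tolerance = 1e-15)
  # the lambda = 2 eigenvector is (e1 - e2)/sqrt(2): entry (1,2) = 2,
  # entries among {3,4} = 0
  E2 <- e_matrix(sp, 2)
  expect_equal(E2[1, 2], 2, tolerance = 1e-10)
  expect_equal(E2[3, 4], 0, tolerance = 1e-10)
  # brute-force double-loop oracle on a random graph
  g <- random_connected_gnp(9, 0.4, 3)
  spg <- eigendecompose(g)
  for (i in c(1, 4, 9)) {
    expect_equal(e_matrix(spg, i), e_matrix_oracle(spg$vectors, i),
                 tolerance = 1e-12)
  }
  expect_error(e_matrix(spg, 10), "out of range")
  # entries bounded by 2, zero diagonal, symmetric
  E <- e_matrix(spg, 5)
  expect_true(all(E >= 0 & E <= 2 + 1e-9))
  expect_equal(diag(E), rep(0, 9))
  expect_equal(E, t(E))
})

test_that("S matrices satisfy the recursion, monotonicity and the S_2 identity", {
  g <- random_connected_gnp(10, 0.4, 7)
  sp <- eigendecompose(g)
  n <- 10
  # S_n - S_{n+1} = E_{lambda_n}
  for (k in c(2, 5, 9)) {
    expect_equal(s_matrix_at(sp, k) - s_matrix_at(sp, k + 1), e_matrix(sp, k),
                 tolerance = 1e-10)
  }
  # entrywise nonincreasing in n
  for (k in seq_len(n - 1)) {
    expect_true(all(s_matrix_at(sp, k) - s_matrix_at(sp, k + 1) >= -1e-12))
  }
  # all off-diagonal entries of S_2 = S_1 equal 2
  S2 <- s_matrix_at(sp, 2)
  expect_lt(max(abs(S2[upper.tri(S2)] - 2)), 1e-8)
  expect_equal(s_matrix_at(sp, 1), S2, tolerance = 1e-10)
})

test_that("detection reproduces the worked transition sequences", {
  # F4: cluster {3,4} forms at 1/4; {1,2} only co-synchronizes at the
  # global threshold 1/2
  plan <- detect_transition(eigendecompose(f4_graph()))
  expect_equal(length(plan$events), 2L)
  expect_equal(plan$events[[1]]$nodes, c("3", "4"))
  expect_equal(plan$events[[1]]$event_type, "formation")
  expect_equal(plan$events[[1]]$relative_coupling, 1 / 4, tolerance = 1e-9)
  expect_equal(plan$events[[2]]$event_type, "complete")
  expect_equal(plan$events[[2]]$relative_coupling, 1 / 2, tolerance = 1e-9)
  expect_equal(sort(plan$events[[2]]$nodes), as.character(1:4))

  # complete graph: a single complete event at 1/N
  plank <- detect_transition(eigendecompose(k_complete(5)))
  expect_equal(length(plank$events), 1L)
  expect_equal(plank$events[[1]]$event_type, "complete")
  expect_equal(plank$events[[1]]$relative_coupling, 1 / 5, tolerance = 1e-9)

  # ten-node orbit graph: formation {7..10} at 1/6, growth +{4,5,6} at 1/4,
  # complete at 1
  plan10 <- detect_transition(eigendecompose(ten_node_orbit_graph()))
  expect_equal(length(plan10$events), 3L)
  expect_equal(sort(plan10$events[[1]]$nodes), c("10", "7", "8", "9"))
  expect_equal(plan10$events[[1]]$event_type, "formation")
  expect_equal(plan10$events[[1]]$relative_coupling, 1 / 6, tolerance = 1e-8)
  expect_equal(sort(plan10$events[[2]]$nodes),
               sort(as.character(4:10)))
  expect_equal(plan10$events[[2]]$event_type, "growth")
  expect_equal(plan10$events[[2]]$relative_coupling, 1 / 4, tolerance = 1e-8)
  expect_equal(plan10$events[[3]]$event_type, "complete")
  expect_equal(plan10$events[[3]]$relative_coupling, 1, tolerance = 1e-8)

  # events are ordered by nondecreasing relative coupling and end complete
  for (p in list(plan, plank, plan10)) {
    rc <- vapply(p$events, `[[`, 0.0, "relative_coupling")
    expect_true(all(diff(rc) >= -1e-12))
    last <- p$events[[length(p$events)]]
    expect_equal(last$event_type, "complete")
    expect_equal(length(last$nodes), length(p$labels))
  }
})

test_that("scaling a plan multiplies by nu* and applies the Class III bound", {
  plan10 <- detect_transition(eigendecompose(ten_node_orbit_graph()))
  scaled_r <- scale_plan(plan10, 0.179)
  expect_equal(vapply(scaled_r$events, `[[`, 0.0, "absolute_coupling"),
               c(0.179 / 6, 0.179 / 4, 0.179), tolerance = 1e-6)
  scaled_l <- scale_plan(plan10, 7.322)
  expect_equal(vapply(scaled_l$events, `[[`, 0.0, "absolute_coupling"),
               c(1.220, 1.8305, 7.322), tolerance = 1e-3)
  expect_true(all(vapply(scaled_r$events, `[[`, TRUE, "reachable")))

  # Class III bound: event at lambda = 0.4 with nu1* = 1 gives d = 2.5,
  # above d_max = nu2*/lambda_N = 5/10 -> unreachable
  toy <- plan10
  toy$events <- list(list(nodes = c("1", "2"), block_eigenvalue = 0.4,
                          relative_coupling = 1 / 0.4,
                          absolute_coupling = NA_real_,
                          event_type = "formation", merged_from = list(),
                          reachable = TRUE))
  cls3 <- structure(list(class_label = "III", nu_star = NULL, nu1_star = 1,
                         nu2_star = 5, curve = NULL),
                    class = "msf_classification")
  scaled3 <- scale_plan(toy, cls3, lambda_N = 10)
  expect_equal(scaled3$events[[1]]$absolute_coupling, 2.5)
  expect_false(scaled3$events[[1]]$reachable)

  # error contracts
  expect_error(scale_plan(plan10, 0), "positive")
  expect_error(scale_plan(plan10, -1), "positive")
  cls1 <- structure(list(class_label = "I"), class = "msf_classification")
  expect_error(scale_plan(plan10, cls1), "defy synchronization")
})

test_that("equitable cells match hand-derived partitions", {
  cells4 <- equitable_cells(f4_graph())$cells
  expect_equal(cells4, list(c("1", "2"), c("3", "4")))
  # path 1-2-3: outer nodes {1,3} receive the same input from node 2
  cells3 <- equitable_cells(p3_graph())$cells
  expect_equal(cells3, list(c("1", "3"), "2"))
  # all-distinct weights: only singletons
  A <- matrix(0, 4, 4)
  w <- c(1, 2.2, 3.7)
  for (i in 1:3) { A[i, i + 1] <- w[i]; A[i + 1, i] <- w[i] }
  cellsw <- equitable_cells(weighted_graph(A))$cells
  expect_true(all(lengths(cellsw) == 1L))
  # orbit graph: the three orbits
  cells10 <- equitable_cells(ten_node_orbit_graph())$cells
  expect_equal(cells10, list(c("1", "2", "3"), c("4", "5", "6"),
                             c("7", "8", "9", "10")))
})

test_that("plans are verified against the cell condition", {
  g <- f4_graph()
  plan <- detect_transition(eigendecompose(g))
  expect_true(verify_plan(plan, g)$ok)
  # corrupt one event: {2,3} is not a cell of F4
  bad <- plan
  bad$events[[1]]$nodes <- c("2", "3")
  rep <- verify_plan(bad, g)
  expect_false(rep$ok)
  expect_equal(rep$violations[[1]]$nodes, c("2", "3"))
})

test_that("detection agrees with planted ground truth and equitable cells", {
  for (seed in c(5, 23)) {
    pg <- planted_cluster_graph(40, list(cluster_spec(6, 3),
                                         cluster_spec(4, 2)),
                                seed = seed, check_cells = TRUE)
    sp <- eigendecompose(pg$graph)
    plan <- detect_transition(sp)
    noncomplete <- Filter(function(e) e$event_type != "complete", plan$events)
    found <- lapply(noncomplete, function(e) sort(e$nodes))
    planted <- lapply(pg$planted_cells, sort)
    expect_equal(found[order(vapply(found, `[[`, "", 1))],
                 planted[order(vapply(planted, `[[`, "", 1))])
    # eigenvalue of each event equals the planted external degree
    ev <- vapply(noncomplete, `[[`, 0.0, "block_eigenvalue")
    expect_equal(sort(ev), sort(pg$expected$eigenvalue), tolerance = 1e-8)
    # the nontrivial equitable cells are exactly the planted ones
    cells <- Filter(function(x) length(x) > 1, equitable_cells(pg$graph)$cells)
    expect_equal(lapply(cells, sort)[order(vapply(cells, `[[`, "", 1))],
                 planted[order(vapply(planted, `[[`, "", 1))])
    expect_true(verify_plan(plan, pg$graph)$ok)
  }
})

test_that("plan JSON serialization carries all event fields", {
  plan <- scale_plan(detect_transition(eigendecompose(f4_graph())), 0.179)
  json <- plan_to_json(plan)
  parsed <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  expect_equal(parsed$schema_version, 1L)
  expect_equal(length(parsed$events), 2L)
  expect_equal(unlist(parsed$events[[1]]$nodes), c("3", "4"))
  expect_equal(parsed$events[[1]]$absolute_coupling, 0.179 / 4,
               tolerance = 1e-12)
  expect_true(parsed$events[[1]]$reachable)
})
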