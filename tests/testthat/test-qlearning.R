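zero_risk <- function(dims, spacing = c(1, 1, 1)) {
  risk_volume(array(0, dim = dims), spacing)
}

test_that("init_qtable fills adjacent pairs and reads -1 elsewhere", {
  cfg6 <- qlearn_config(connectivity = 6, seed = 3)
  q <- init_qtable(zero_risk(c(2, 1, 1)), cfg6)
  expect_equal(sum(q$valid), 2L)
  expect_gte(q_value(q, c(0, 0, 0), c(1, 0, 0)), 0)
  expect_lt(q_value(q, c(0, 0, 0), c(1, 0, 0)), 1)
  expect_gte(q_value(q, c(1, 0, 0), c(0, 0, 0)), 0)
  # any other query reads the no-transition sentinel
  expect_equal(q_value(q, c(0, 0, 0), c(0, 0, 0)), -1)
  expect_equal(q_value(q, c(0, 0, 0), c(5, 0, 0)), -1)

  q1 <- init_qtable(zero_risk(c(1, 1, 1)), cfg6)
  expect_equal(sum(q1$valid), 0L)

  q26 <- init_qtable(zero_risk(c(3, 3, 3)), qlearn_config(seed = 3))
  center <- qpath:::vox_to_lin(matrix(c(1L, 1L, 1L), 1), c(3L, 3L, 3L))
  expect_equal(sum(q26$valid[center, ]), 26L)
})

test_that("the same seed reproduces the initial Q-table bit for bit", {
  rv <- zero_risk(c(4, 4, 4))
  q1 <- init_qtable(rv, qlearn_config(seed = 11))
  q2 <- init_qtable(rv, qlearn_config(seed = 11))
  q3 <- init_qtable(rv, qlearn_config(seed = 12))
  expect_identical(q1$q, q2$q)
  expect_false(identical(q1$q, q3$q))
})

test_that("bellman_update applies the penalty-minimizing rule", {
  rv <- zero_risk(c(3, 1, 1))
  cfg <- qlearn_config(alpha = 0.1, gamma = 0.9, connectivity = 6, seed = 1)
  q <- init_qtable(rv, cfg)
  s <- c(0, 0, 0); a <- c(1, 0, 0)
  # pin the entries the update reads
  q$q[qpath:::vox_to_lin(matrix(as.integer(s), 1), q$dims),
      qpath:::match_move(q$offsets, as.integer(a - s))] <- 0.5
  al <- qpath:::vox_to_lin(matrix(as.integer(a), 1), q$dims)
  q$q[al, q$valid[al, ]] <- c(1.0, 1.3)  # best_next = 1.0
  v <- bellman_update(q, s, a, penalty = 0.2, config = cfg)
  expect_equal(v, 0.5 + 0.1 * (0.2 + 0.9 * 1.0 - 0.5))
  expect_equal(q_value(q, s, a), v)  # stored in place

  # alpha = 1 with a terminal next state overwrites with the penalty
  cfg1 <- qlearn_config(alpha = 1, connectivity = 6, seed = 1)
  q2 <- init_qtable(rv, cfg1)
  expect_equal(bellman_update(q2, s, a, penalty = 1, config = cfg1,
                              terminal = TRUE), 1)

  # alpha = 0 leaves the value unchanged
  cfg0 <- qlearn_config(alpha = 1, connectivity = 6, seed = 1)
  q3 <- init_qtable(rv, cfg0)
  before <- q_value(q3, s, a)
  cfg0$alpha <- 0
  expect_equal(bellman_update(q3, s, a, penalty = 7, config = cfg0), before)

  # updating a -1 (non-adjacent) entry is an error
  expect_error(bellman_update(q2, c(0, 0, 0), c(2, 0, 0), 0.1, cfg1),
               "no transition")
})

test_that("training solves the free_line fixture exactly", {
  tc <- generate_toy_case("free_line")
  qt <- qlearn_train(tc$risk, tc$entry, tc$target, tc$config)
  path <- extract_path(qt, tc$entry, tc$target)
  expect_equal(unclass(path),
               cbind(0L, 0L, 0:4), ignore_attr = TRUE)
  expect_equal(path_penalty_cost(path, tc$risk, tc$config), tc$oracle_cost)
  expect_equal(tc$oracle_cost, 0.04)
})

test_that("q_score telescopes the converged cost-to-go along the path", {
  tc <- generate_toy_case("free_line")
  qt <- qlearn_train(tc$risk, tc$entry, tc$target, tc$config)
  path <- extract_path(qt, tc$entry, tc$target)
  V <- vi_cost_to_go(tc$risk, tc$target, tc$config$connectivity,
                     tc$config$step_cost)
  dims <- dim(tc$risk$risk)
  expected <- 0
  for (i in seq_len(nrow(path) - 1)) {
    v <- path[i + 1, , drop = FALSE]
    expected <- expected + tc$config$step_cost +
      tc$risk$risk[qpath:::vox_to_lin(v, dims)] +
      V[qpath:::vox_to_lin(v, dims)]
  }
  expect_equal(q_score(qt, path), expected, tolerance = 1e-12)
  expect_equal(q_score(qt, path), 0.1, tolerance = 1e-12)
})

test_that("the planner detours around the risky center block", {
  tc <- generate_toy_case("center_block")
  res <- qlearn_plan(tc$risk, tc$entry, tc$target, tc$config)
  expect_false(any(res$path[, 1] == 1L & res$path[, 2] == 1L))
  expect_equal(res$penalty_cost, 0.03)
  expect_equal(res$qr_score, 0)
  # independent exhaustive enumeration agrees
  expect_equal(brute_force_min_cost(tc$risk, tc$entry, tc$target), 0.03)
})

test_that("the optimal path threads the gap in the wall", {
  tc <- generate_toy_case("wall_with_gap")
  wall_cols <- tc$oracle_path[tc$oracle_path[, 1] == 2L, , drop = FALSE]
  expect_equal(nrow(wall_cols), 1L)
  expect_equal(wall_cols[1, ], c(2L, 2L, 0L))
  res <- qlearn_plan(tc$risk, tc$entry, tc$target, tc$config)
  crossing <- res$path[res$path[, 1] == 2L, , drop = FALSE]
  expect_equal(crossing[1, ], c(2L, 2L, 0L))
  expect_equal(res$penalty_cost, tc$oracle_cost)
})

test_that("an entry adjacent to the target yields a two-voxel path", {
  rv <- zero_risk(c(3, 3, 3))
  res <- qlearn_plan(rv, c(0, 0, 0), matrix(c(1, 1, 1), 1),
                     qlearn_config(seed = 5, episodes_max = 500))
  expect_equal(nrow(res$path), 2L)
  expect_equal(res$penalty_cost, 0.01)
})

test_that("extract_path handles the degenerate entry-in-target case", {
  q <- init_qtable(zero_risk(c(3, 3, 3)), qlearn_config(seed = 1))
  p <- extract_path(q, c(1, 1, 1), matrix(c(1, 1, 1), 1))
  expect_equal(nrow(p), 1L)
  expect_equal(q_score(q, p), 0)
})

test_that("q_score sums transition values and rejects broken paths", {
  cfg <- qlearn_config(connectivity = 6, seed = 2)
  q <- init_qtable(zero_risk(c(3, 1, 1)), cfg)
  dims <- q$dims
  q$q[qpath:::vox_to_lin(matrix(c(0L, 0L, 0L), 1), dims),
      qpath:::match_move(q$offsets, c(1L, 0L, 0L))] <- 0.2
  q$q[qpath:::vox_to_lin(matrix(c(1L, 0L, 0L), 1), dims),
      qpath:::match_move(q$offsets, c(1L, 0L, 0L))] <- 0.3
  path <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(q_score(q, path), 0.5)
  expect_error(q_score(q, rbind(c(0, 0, 0), c(2, 0, 0))), "invalid path")
})

test_that("dijkstra_oracle is exact on tiny grids (exhaustive cross-check)", {
  set.seed(31)
  cfg <- qlearn_config(seed = 1)
  for (trial in 1:6) {
    rv <- random_risk_volume(c(3, 3, 2), spacing = c(1, 1, 1))
    orc <- dijkstra_oracle(rv, c(0, 0, 0), matrix(c(2, 2, 1), 1), cfg)
    expect_equal(orc$cost,
                 brute_force_min_cost(rv, c(0, 0, 0), c(2, 2, 1)),
                 label = paste("trial", trial))
    expect_equal(path_penalty_cost(orc$path, rv, cfg), orc$cost)
  }
})

test_that("dijkstra_oracle honors barriers and reports unreachable targets", {
  a <- array(0, dim = c(3, 3, 1))
  a[2, , 1] <- 1  # full wall
  rv <- risk_volume(a, c(1, 1, 1))
  cfg <- qlearn_config(barrier_threshold = 0.5)
  expect_error(dijkstra_oracle(rv, c(0, 0, 0), matrix(c(2, 0, 0), 1), cfg),
               "unreachable")
  # without the barrier the wall is merely expensive
  free <- dijkstra_oracle(rv, c(0, 0, 0), matrix(c(2, 0, 0), 1),
                          qlearn_config())
  expect_equal(free$cost, 1.02)
})

test_that("training errors when barriers make the target unreachable", {
  a <- array(0, dim = c(3, 3, 1))
  a[2, , 1] <- 1
  rv <- risk_volume(a, c(1, 1, 1))
  cfg <- qlearn_config(barrier_threshold = 0.5, episodes_max = 50, seed = 4)
  expect_error(qlearn_train(rv, c(0, 0, 0), matrix(c(2, 0, 0), 1), cfg),
               "unreachable")
})

test_that("plans are bit-identical across repeated runs with one seed", {
  set.seed(99)
  rv <- random_risk_volume(c(8, 8, 8))
  cfg <- qlearn_config(seed = 17, episodes_max = 3000)
  r1 <- qlearn_plan(rv, c(0, 0, 0), matrix(c(6, 6, 6), 1), cfg)
  r2 <- qlearn_plan(rv, c(0, 0, 0), matrix(c(6, 6, 6), 1), cfg)
  expect_identical(r1, r2)
  expect_equal(r1$qr_score, path_total_risk(r1$path, rv))
})

test_that("trained greedy paths match the oracle on small random volumes", {
  set.seed(123)
  for (trial in 1:5) {
    rv <- random_risk_volume(c(7, 7, 7))
    cfg <- qlearn_config(seed = trial, episodes_max = 100000L,
                         stable_episodes = 10000L, epsilon_min = 0.5)
    orc <- dijkstra_oracle(rv, c(0, 3, 3), matrix(c(5, 3, 3), 1), cfg)
    res <- qlearn_plan(rv, c(0, 3, 3), matrix(c(5, 3, 3), 1), cfg)
    expect_equal(res$penalty_cost, orc$cost, label = paste("trial", trial))
    # adjacency contract along the returned path
    steps <- diff(res$path)
    expect_true(all(abs(steps) <= 1L))
    expect_true(all(rowSums(abs(steps)) >= 1L))
  }
})

test_that("raising one voxel's risk never lowers the oracle cost", {
  set.seed(77)
  rv <- random_risk_volume(c(6, 6, 6), values = c(0, 0.3, 0.7))
  cfg <- qlearn_config()
  entry <- c(0, 0, 0); target <- matrix(c(5, 5, 5), 1)
  base <- dijkstra_oracle(rv, entry, target, cfg)$cost
  for (i in 1:10) {
    v <- sapply(c(6, 6, 6), function(d) sample(0:(d - 1), 1))
    rv2 <- rv
    lin <- qpath:::vox_to_lin(matrix(as.integer(v), 1), c(6L, 6L, 6L))
    rv2$risk[lin] <- min(1, rv2$risk[lin] + 0.3)
    expect_gte(dijkstra_oracle(rv2, entry, target, cfg)$cost, base - 1e-12)
  }
})
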