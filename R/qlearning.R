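#' Q-learning planner configuration
#'
#' Hyperparameters of the tabular Q-learning path-finder and of the exact
#' Dijkstra oracle that validates it. The Q-table holds a value per
#' (voxel, adjacent voxel) pair; the update is the penalty-minimizing
#' Bellman rule `Q(S,A) <- Q(S,A) + alpha * (R + gamma * best_next - Q(S,A))`
#' with `best_next` the minimum finite Q at the destination voxel and
#' per-step penalty `R = step_cost + risk(destination)`. Lower Q is better.
#'
#' @param alpha learning rate in (0, 1]. Default 1: transitions and
#'   penalties on a voxel grid are deterministic, so the full-overwrite
#'   update is exact asynchronous value iteration and converges to the
#'   optimal cost-to-go.
#' @param gamma discount factor in (0, 1]. Default 1 (undiscounted total
#'   penalty, the quantity the reports sum).
#' @param epsilon_start,epsilon_min,epsilon_decay epsilon-greedy
#'   exploration schedule: per-episode epsilon decays geometrically from
#'   `epsilon_start` to `epsilon_min`.
#' @param episodes_max maximum training episodes.
#' @param stable_episodes early stop once the greedy entry-to-target path
#'   is unchanged for this many consecutive episodes.
#' @param step_cost non-negative per-move base penalty added to the
#'   destination voxel's risk, so zero-risk plateaus still prefer shorter
#'   corridors. Default 0.01.
#' @param barrier_threshold optional risk level in (0, 1]; voxels at or
#'   above it are removed from the graph. `NULL` (default) penalizes risky
#'   structures rather than forbidding them.
#' @param connectivity 6 (faces) or 26 (faces+edges+corners, default).
#' @param seed integer seed for Q-table initialization and exploration;
#'   fixing it makes the whole pipeline reproducible.
#' @param goal_terminal if `TRUE` (default) the target region is absorbing
#'   and `best_next` at a target voxel is 0.
#' @param scale_diagonal if `TRUE`, each move's `step_cost` is multiplied
#'   by its mm length, so diagonal steps cost more; default `FALSE` (the
#'   penalty is purely risk-based).
#' @param step_cap per-episode step limit; default `4 * sum(dims)`,
#'   resolved at training time.
#' @return A `qlearn_config` list.
#' @export
qlearn_config <- function(alpha = 1, gamma = 1, epsilon_start = 1,
                          epsilon_min = 0.05, epsilon_decay = 0.995,
                          episodes_max = 2000L, stable_episodes = 100L,
                          step_cost = 0.01, barrier_threshold = NULL,
                          connectivity = 26, seed = 1L,
                          goal_terminal = TRUE, scale_diagonal = FALSE,
                          step_cap = NULL) {
  stopifnot(alpha > 0, alpha <= 1, gamma > 0, gamma <= 1,
            epsilon_start >= 0, epsilon_start <= 1,
            epsilon_min >= 0, epsilon_min <= 1,
            epsilon_decay > 0, epsilon_decay <= 1,
            episodes_max >= 1, stable_episodes >= 1, step_cost >= 0)
  if (!is.null(barrier_threshold))
    stopifnot(barrier_threshold > 0, barrier_threshold <= 1)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  structure(list(alpha = alpha, gamma = gamma,
                 epsilon_start = epsilon_start, epsilon_min = epsilon_min,
                 epsilon_decay = epsilon_decay,
                 episodes_max = as.integer(episodes_max),
                 stable_episodes = as.integer(stable_episodes),
                 step_cost = step_cost, barrier_threshold = barrier_threshold,
                 connectivity = connectivity, seed = as.integer(seed),
                 goal_terminal = isTRUE(goal_terminal),
                 scale_diagonal = isTRUE(scale_diagonal),
                 step_cap = if (is.null(step_cap)) NULL else as.integer(step_cap)),
            class = "qlearn_config")
}

# Per-move step-cost multipliers (mm length when scale_diagonal, else 1).
move_multipliers <- function(offsets, spacing_mm, scale_diagonal) {
  if (!scale_diagonal) return(rep(1, nrow(offsets)))
  sqrt(rowSums(sweep(offsets, 2, spacing_mm, "*")^2))
}

# Adjacency structure shared by the planner and the oracle: which of the
# lexicographically ordered moves are admissible from each voxel, and the
# linear index of the voxel each admissible move reaches.
build_adjacency <- function(risk, config) {
  dims <- dim(risk$risk)
  offsets <- conn_offsets(config$connectivity)
  n <- prod(dims)
  node_ok <- rep(TRUE, n)
  if (!is.null(config$barrier_threshold))
    node_ok <- as.vector(risk$risk) < config$barrier_threshold
  co <- arrayInd(seq_len(n), dims) - 1L
  m <- nrow(offsets)
  valid <- matrix(FALSE, n, m)
  nbr <- matrix(1L, n, m)
  for (mm in seq_len(m)) {
    ni <- co[, 1] + offsets[mm, 1]; nj <- co[, 2] + offsets[mm, 2]
    nk <- co[, 3] + offsets[mm, 3]
    inb <- ni >= 0L & ni < dims[1] & nj >= 0L & nj < dims[2] &
           nk >= 0L & nk < dims[3]
    lin <- pmax(ni, 0L) + dims[1] * (pmax(nj, 0L) + dims[2] * pmax(nk, 0L)) + 1L
    lin <- pmin(lin, n)
    ok <- inb & node_ok & node_ok[lin]
    valid[, mm] <- ok
    nbr[ok, mm] <- lin[ok]
  }
  list(valid = valid, nbr = nbr, offsets = offsets, dims = dims,
       node_ok = node_ok,
       mult = move_multipliers(offsets, risk$spacing_mm, config$scale_diagonal))
}

#' Initialize a Q-table over the voxel adjacency graph
#'
#' For every ordered pair of adjacent voxels (under the configured
#' connectivity, excluding any barrier voxels) the table entry is drawn
#' uniformly from \[0, 1) using the configured seed; every non-adjacent
#' pair reads -1, the no-transition sentinel. The same seed reproduces the
#' same table bit for bit.
#'
#' @param risk a [risk_volume()].
#' @param config a [qlearn_config()].
#' @return A `qtable` (environment-backed so that updates are in place).
#' @export
init_qtable <- function(risk, config = qlearn_config()) {
  stopifnot(inherits(risk, "risk_volume"), inherits(config, "qlearn_config"))
  with_seed(config$seed, init_qtable_impl(risk, config))
}

# Draws from the current RNG stream (caller controls seeding).
init_qtable_impl <- function(risk, config) {
  adj <- build_adjacency(risk, config)
  q <- matrix(-1, nrow(adj$valid), ncol(adj$valid))
  q[adj$valid] <- stats::runif(sum(adj$valid))
  e <- new.env(parent = emptyenv())
  e$q <- q
  e$valid <- adj$valid
  e$nbr <- adj$nbr
  e$offsets <- adj$offsets
  e$dims <- adj$dims
  e$mult <- adj$mult
  e$spacing_mm <- risk$spacing_mm
  e$config <- config
  class(e) <- c("qtable", "environment")
  e
}

#' @export
print.qtable <- function(x, ...) {
  cat(sprintf("<qtable> %s grid, %d-connectivity, %d finite entries\n",
              paste(x$dims, collapse = " x "), x$config$connectivity,
              sum(x$valid)))
  invisible(x)
}

#' Read a Q-value for an ordered (voxel, neighbor) pair
#'
#' @param q a `qtable`.
#' @param u,v 0-based voxel index triplets.
#' @return The stored Q-value, or -1 if `v` is not adjacent to `u` (or
#'   either voxel is outside the grid / barred).
#' @export
q_value <- function(q, u, v) {
  stopifnot(inherits(q, "qtable"))
  u <- as_voxel_matrix(u); v <- as_voxel_matrix(v)
  if (!in_bounds(u, q$dims) || !in_bounds(v, q$dims)) return(-1)
  mv <- match_move(q$offsets, v - u)
  if (is.na(mv)) return(-1)
  q$q[vox_to_lin(u, q$dims), mv]
}

match_move <- function(offsets, d) {
  hits <- which(offsets[, 1] == d[1] & offsets[, 2] == d[2] &
                offsets[, 3] == d[3])
  if (length(hits) == 1L) hits else NA_integer_
}

#' One Bellman update on a Q-table entry
#'
#' Applies the penalty-minimizing temporal-difference rule
#' `Q(s,a) <- Q(s,a) + alpha * (R + gamma * best_next - Q(s,a))` where
#' `best_next` is the minimum finite Q among moves out of `a` (0 when `a`
#' is terminal or has no finite successor). Updating a -1 (no-transition)
#' entry is an error.
#'
#' @param q a `qtable` (modified in place).
#' @param s current voxel (0-based triplet).
#' @param a adjacent destination voxel.
#' @param penalty the per-step penalty R (typically
#'   `step_cost + risk(a)`).
#' @param config a [qlearn_config()] supplying `alpha` and `gamma`.
#' @param terminal is `a` an absorbing target voxel?
#' @return The updated Q-value, invisibly stored in `q`.
#' @export
bellman_update <- function(q, s, a, penalty, config = q$config,
                           terminal = FALSE) {
  stopifnot(inherits(q, "qtable"))
  s <- as_voxel_matrix(s); a <- as_voxel_matrix(a)
  mv <- match_move(q$offsets, a - s)
  sl <- vox_to_lin(s, q$dims)
  if (is.na(mv) || !q$valid[sl, mv])
    stop("no transition between the given voxels (Q reads -1)")
  best_next <- 0
  if (!terminal) {
    al <- vox_to_lin(a, q$dims)
    fin <- q$q[al, q$valid[al, ]]
    if (length(fin) > 0) best_next <- min(fin)
  }
  new <- q$q[sl, mv] +
    config$alpha * (penalty + config$gamma * best_next - q$q[sl, mv])
  q$q[sl, mv] <- new
  new
}

resolve_plan_endpoints <- function(risk, entry, target, config) {
  dims <- dim(risk$risk)
  entry <- as_voxel_matrix(entry)
  target <- as_voxel_matrix(target)
  if (nrow(entry) != 1L) stop("entry must be a single voxel")
  if (nrow(target) < 1L) stop("target must be a non-empty set of voxels")
  if (!all(in_bounds(rbind(entry, target), dims)))
    stop("entry/target voxel out of bounds")
  target <- unique(lex_sort_voxels(target))
  list(entry = entry, target = target,
       entry_lin = vox_to_lin(entry, dims),
       target_lin = vox_to_lin(target, dims))
}

resolve_step_cap <- function(config, dims) {
  if (!is.null(config$step_cap)) config$step_cap else 4L * sum(dims)
}

#' Train a Q-table by episodic epsilon-greedy search
#'
#' Runs episodes from the entry voxel: each step picks a random admissible
#' move with probability epsilon, otherwise the minimum-Q move, applies
#' [bellman_update()], and ends on reaching the target region or on the
#' step cap. Training stops at `episodes_max` or as soon as the greedy
#' entry-to-target path has been unchanged for `stable_episodes`
#' consecutive episodes. All randomness flows from `config$seed`.
#'
#' @param risk a [risk_volume()].
#' @param entry 0-based entry voxel (must not be in the target).
#' @param target n x 3 matrix (or single triplet) of target voxels.
#' @param config a [qlearn_config()].
#' @return The trained `qtable`, with attributes `episodes_run`,
#'   `converged` and `greedy_costs` (per-episode penalty cost of the greedy
#'   path, `NA` until it first reaches the target) stored in the object.
#' @export
qlearn_train <- function(risk, entry, target, config = qlearn_config()) {
  stopifnot(inherits(risk, "risk_volume"), inherits(config, "qlearn_config"))
  ep <- resolve_plan_endpoints(risk, entry, target, config)
  if (any(ep$entry_lin == ep$target_lin))
    stop("entry must not lie inside the target region")
  res <- NULL
  qt <- NULL
  with_seed(config$seed, {
    qt <- init_qtable_impl(risk, config)
    if (!is.null(config$barrier_threshold)) {
      lin <- c(ep$entry_lin, ep$target_lin)
      if (any(as.vector(risk$risk)[lin] >= config$barrier_threshold))
        stop("entry or target voxel is excluded by barrier_threshold")
    }
    is_target <- rep(FALSE, prod(qt$dims))
    is_target[ep$target_lin] <- TRUE
    res <- train_q_cpp(
      qt$q, qt$valid, qt$nbr, as.vector(risk$risk), is_target,
      ep$entry_lin, config$alpha, config$gamma, config$epsilon_start,
      config$epsilon_min, config$epsilon_decay, config$episodes_max,
      config$stable_episodes, config$step_cost, qt$mult,
      config$goal_terminal, resolve_step_cap(config, qt$dims))
  })
  if (res$completed_episodes == 0L && !res$converged)
    stop("target unreachable: no episode reached it within episodes_max")
  qt$q <- res$q
  qt$episodes_run <- res$episodes_run
  qt$converged <- res$converged
  qt$greedy_costs <- res$greedy_costs
  qt
}

#' Extract the greedy path from a trained Q-table
#'
#' Greedy descent from the entry voxel, at each step taking the move with
#' the minimum finite Q-value (ties broken by lexicographic neighbor
#' order), until a target voxel is reached. Revisiting a voxel or running
#' out of admissible moves raises a non-convergence error.
#'
#' @param q a trained `qtable`.
#' @param entry 0-based entry voxel.
#' @param target n x 3 matrix (or triplet) of target voxels.
#' @return A `voxel_path`: an ordered n x 3 integer matrix of 0-based
#'   voxel indices with consecutive rows adjacent.
#' @export
extract_path <- function(q, entry, target) {
  stopifnot(inherits(q, "qtable"))
  dims <- q$dims
  entry <- as_voxel_matrix(entry)
  target <- as_voxel_matrix(target)
  if (!all(in_bounds(rbind(entry, target), dims)))
    stop("entry/target voxel out of bounds")
  tset <- vox_to_lin(target, dims)
  u <- vox_to_lin(entry, dims)
  if (u %in% tset) return(new_voxel_path(entry))
  n <- prod(dims)
  seen <- logical(n)
  seen[u] <- TRUE
  path <- integer(n)
  path[1] <- u
  len <- 1L
  repeat {
    fin <- which(q$valid[u, ])
    if (length(fin) == 0L)
      stop("non-convergence: dead end at voxel ",
           paste(lin_to_vox(u, dims), collapse = ","))
    mv <- fin[which.min(q$q[u, fin])]
    v <- q$nbr[u, mv]
    if (seen[v])
      stop("non-convergence: cycle detected at voxel ",
           paste(lin_to_vox(v, dims), collapse = ","))
    len <- len + 1L
    path[len] <- v
    seen[v] <- TRUE
    u <- v
    if (u %in% tset) break
    if (len >= n) stop("non-convergence: path exceeded grid size")
  }
  new_voxel_path(lin_to_vox(path[seq_len(len)], dims))
}

new_voxel_path <- function(vox) {
  vox <- as_voxel_matrix(vox)
  structure(vox, class = "voxel_path")
}

#' @export
print.voxel_path <- function(x, ...) {
  cat(sprintf("<voxel_path> %d voxels from (%s) to (%s)\n", nrow(x),
              paste(x[1, ], collapse = ","),
              paste(x[nrow(x), ], collapse = ",")))
  invisible(x)
}

#' Q-learning score of a path
#'
#' The sum of the Q-table entries along the path's transitions,
#' `sum_i q(node_i, node_{i+1})`; the score the comparison reports rank by
#' (lower is better). A single-voxel path scores 0; a -1 (no-transition)
#' entry anywhere on the path is an error.
#'
#' @param q a `qtable`.
#' @param path a `voxel_path` or n x 3 index matrix.
#' @return The summed Q-value.
#' @export
q_score <- function(q, path) {
  stopifnot(inherits(q, "qtable"))
  vox <- mask_voxels(path)
  if (nrow(vox) <= 1L) return(0)
  total <- 0
  for (i in seq_len(nrow(vox) - 1L)) {
    val <- q_value(q, vox[i, ], vox[i + 1L, ])
    if (val == -1)
      stop("invalid path: no transition between consecutive voxels ",
           i, " and ", i + 1L)
    total <- total + val
  }
  total
}

#' Penalty cost of a path under the planner's objective
#'
#' `sum over steps of (step_cost * move_multiplier + risk(destination))`,
#' i.e. the quantity both the Q-learning planner and the Dijkstra oracle
#' minimize. The entry voxel's own risk is not charged (no move enters it).
#'
#' @param path a `voxel_path` or n x 3 index matrix of consecutive adjacent
#'   voxels.
#' @param risk a [risk_volume()].
#' @param config a [qlearn_config()] supplying `step_cost` and diagonal
#'   scaling.
#' @return The penalty cost.
#' @export
path_penalty_cost <- function(path, risk, config = qlearn_config()) {
  stopifnot(inherits(risk, "risk_volume"))
  vox <- mask_voxels(path)
  if (nrow(vox) <= 1L) return(0)
  dims <- dim(risk$risk)
  if (!all(in_bounds(vox, dims))) stop("path voxel out of bounds")
  steps <- vox[-1L, , drop = FALSE] - vox[-nrow(vox), , drop = FALSE]
  if (any(abs(steps) > 1L)) stop("consecutive path voxels are not adjacent")
  mult <- if (config$scale_diagonal)
    sqrt(rowSums(sweep(steps, 2, risk$spacing_mm, "*")^2))
  else rep(1, nrow(steps))
  sum(config$step_cost * mult) +
    sum(risk$risk[vox_to_lin(vox[-1L, , drop = FALSE], dims)])
}

#' Plan a minimum-penalty corridor with Q-learning
#'
#' Composes [qlearn_train()], [extract_path()], [q_score()] and
#' [path_total_risk()]. With a fixed seed the result is fully reproducible.
#'
#' @inheritParams qlearn_train
#' @return A `plan_result`: list with `path` (a `voxel_path`), `q_score`
#'   (summed Q along the path), `qr_score` (arithmetic sum of per-voxel
#'   risk along the path), `penalty_cost`, `converged`, `episodes_run`,
#'   and `greedy_costs` (per-episode convergence log).
#' @export
qlearn_plan <- function(risk, entry, target, config = qlearn_config()) {
  qt <- qlearn_train(risk, entry, target, config)
  path <- extract_path(qt, entry, target)
  structure(list(path = path,
                 q_score = q_score(qt, path),
                 qr_score = path_total_risk(path, risk),
                 penalty_cost = path_penalty_cost(path, risk, config),
                 converged = qt$converged,
                 episodes_run = qt$episodes_run,
                 greedy_costs = qt$greedy_costs),
            class = "plan_result")
}

#' @export
print.plan_result <- function(x, ...) {
  cat(sprintf(paste0("<plan_result> %d voxels, q_score %.4f, qr_score %.4f,",
                     " %s after %d episodes\n"),
              nrow(x$path), x$q_score, x$qr_score,
              if (x$converged) "converged" else "not converged",
              x$episodes_run))
  invisible(x)
}

#' Exact minimum-penalty path by Dijkstra's algorithm
#'
#' The independent optimality oracle: computes the exact minimum of
#' `sum(step_cost * multiplier + risk(v))` over all entry-to-target paths
#' under the configured connectivity and barriers, using shortest-path
#' distances on the voxel adjacency graph (via igraph) and a deterministic
#' lexicographic reconstruction of one optimal path.
#'
#' @inheritParams qlearn_train
#' @return A list with `path` (a `voxel_path`) and `cost`.
#' @export
dijkstra_oracle <- function(risk, entry, target, config = qlearn_config()) {
  stopifnot(inherits(risk, "risk_volume"), inherits(config, "qlearn_config"))
  ep <- resolve_plan_endpoints(risk, entry, target, config)
  dims <- dim(risk$risk)
  if (any(ep$entry_lin == ep$target_lin))
    return(list(path = new_voxel_path(ep$entry), cost = 0))
  adj <- build_adjacency(risk, config)
  if (!adj$node_ok[ep$entry_lin] || !any(adj$node_ok[ep$target_lin]))
    stop("target unreachable: entry or target excluded by barrier_threshold")
  n <- prod(dims)
  rv <- as.vector(risk$risk)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (mm in seq_len(ncol(adj$valid))) {
    src <- which(adj$valid[, mm])
    dst <- adj$nbr[src, mm]
    from <- c(from, src); to <- c(to, dst)
    w <- c(w, config$step_cost * adj$mult[mm] + rv[dst])
  }
  sink <- n + 1L
  tlin <- ep$target_lin[adj$node_ok[ep$target_lin]]
  from <- c(from, tlin); to <- c(to, rep(sink, length(tlin)))
  w <- c(w, rep(0, length(tlin)))
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = sink,
                          directed = TRUE)
  d_to <- as.vector(igraph::distances(g, v = sink, mode = "in", weights = w))
  cost <- d_to[ep$entry_lin]
  if (!is.finite(cost))
    stop("target unreachable from entry under the configured connectivity")
  # lexicographic reconstruction: at each voxel take the smallest-index
  # neighbor v with weight(u->v) + d_to[v] == d_to[u]
  u <- ep$entry_lin
  path <- integer(n); path[1] <- u; len <- 1L
  tol <- 1e-9
  tset <- logical(n); tset[ep$target_lin] <- TRUE
  while (!tset[u]) {
    fin <- which(adj$valid[u, ])
    vs <- adj$nbr[u, fin]
    wts <- config$step_cost * adj$mult[fin] + rv[vs]
    ok <- which(abs(wts + d_to[vs] - d_to[u]) <= tol * (1 + abs(d_to[u])))
    if (length(ok) == 0L) stop("internal error: optimal path reconstruction failed")
    # moves are in lexicographic offset order, so the first hit is the
    # lexicographically smallest optimal neighbor
    v <- vs[ok[1L]]
    len <- len + 1L
    path[len] <- v
    u <- v
    if (len > n) stop("internal error: oracle path exceeded grid size")
  }
  list(path = new_voxel_path(lin_to_vox(path[seq_len(len)], dims)),
       cost = cost)
}
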