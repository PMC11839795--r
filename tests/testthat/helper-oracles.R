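# Independent test oracles, deliberately written without reusing the
# package's adjacency/graph machinery.

# Exhaustive branch-and-bound enumeration of simple paths; exact minimum of
# sum(step_cost + risk(destination)) on tiny grids.
brute_force_min_cost <- function(risk, entry, target, connectivity = 26,
                                 step_cost = 0.01) {
  dims <- dim(risk$risk)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  tmat <- if (is.null(dim(target))) matrix(target, 1) else target
  is_target <- function(v) any(tmat[, 1] == v[1] & tmat[, 2] == v[2] &
                               tmat[, 3] == v[3])
  rv <- risk$risk
  best <- Inf
  rec <- function(v, cost, visited) {
    if (is_target(v)) {
      best <<- min(best, cost)
      return()
    }
    if (cost >= best) return()
    for (m in seq_len(nrow(offs))) {
      w <- v + offs[m, ]
      if (any(w < 0) || any(w > dims - 1)) next
      wl <- w[1] + dims[1] * (w[2] + dims[2] * w[3]) + 1
      if (visited[wl]) next
      vis2 <- visited
      vis2[wl] <- TRUE
      rec(w, cost + step_cost + rv[wl], vis2)
    }
  }
  vis <- logical(prod(dims))
  vis[entry[1] + dims[1] * (entry[2] + dims[2] * entry[3]) + 1] <- TRUE
  rec(as.integer(entry), 0, vis)
  best
}

# Exact cost-to-go per voxel by value iteration (Bellman-Ford sweeps).
vi_cost_to_go <- function(risk, target, connectivity = 26, step_cost = 0.01) {
  dims <- dim(risk$risk)
  n <- prod(dims)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  co <- arrayInd(seq_len(n), dims) - 1L
  rv <- as.vector(risk$risk)
  tmat <- if (is.null(dim(target))) matrix(target, 1) else target
  tlin <- tmat[, 1] + dims[1] * (tmat[, 2] + dims[2] * tmat[, 3]) + 1
  V <- rep(Inf, n)
  V[tlin] <- 0
  repeat {
    Vold <- V
    for (m in seq_len(nrow(offs))) {
      ni <- co[, 1] + offs[m, 1]; nj <- co[, 2] + offs[m, 2]
      nk <- co[, 3] + offs[m, 3]
      inb <- ni >= 0 & ni < dims[1] & nj >= 0 & nj < dims[2] &
             nk >= 0 & nk < dims[3]
      lin <- pmin(pmax(ni, 0) + dims[1] * (pmax(nj, 0) + dims[2] * pmax(nk, 0)) + 1, n)
      cand <- ifelse(inb, step_cost + rv[lin] + V[lin], Inf)
      cand[tlin] <- 0
      V <- pmin(V, cand)
      V[tlin] <- 0
    }
    if (identical(V, Vold)) break
  }
  V
}

# All voxels whose centers lie within diameter/2 of the closed segment, by
# a plain loop-free check over the whole grid (its own distance formula).
brute_cylinder_voxels <- function(entry_mm, target_mm, diameter_mm, dims,
                                  spacing_mm) {
  n <- prod(dims)
  co <- arrayInd(seq_len(n), dims) - 1L
  p <- sweep(co, 2, spacing_mm, "*")
  a <- entry_mm; b <- target_mm
  ab <- b - a
  t <- ((p[, 1] - a[1]) * ab[1] + (p[, 2] - a[2]) * ab[2] +
        (p[, 3] - a[3]) * ab[3]) / sum(ab^2)
  t <- pmin(pmax(t, 0), 1)
  cx <- a[1] + t * ab[1]; cy <- a[2] + t * ab[2]; cz <- a[3] + t * ab[3]
  d2 <- (p[, 1] - cx)^2 + (p[, 2] - cy)^2 + (p[, 3] - cz)^2
  keep <- d2 <= (diameter_mm / 2)^2
  m <- co[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

# Small random risk volume with values drawn from a fixed score set.
random_risk_volume <- function(dims, values = c(0, 0.3, 0.7, 1.0),
                               spacing = c(0.8, 0.8, 0.8)) {
  risk_volume(array(values[sample.int(length(values), prod(dims),
                                      replace = TRUE)], dim = dims), spacing)
}
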