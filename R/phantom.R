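#' Specification for a synthetic labeled phantom
#'
#' Describes a desk-scale stand-in for a segmented brain volume: named
#' Voronoi regions with penalty scores, optional tube-shaped high-risk
#' structures standing in for vessels and fiber tracts, and optional
#' low-risk corridor channels from a surface entry voxel to an interior
#' target. The default 0.8 mm isotropic spacing mirrors a typical
#' high-resolution T1 grid.
#'
#' @param dims integer length-3, voxels per axis, each >= 8.
#' @param spacing_mm numeric length-3 spacing, each > 0.
#' @param n_regions number of Voronoi background regions (>= 1).
#' @param n_tubes number of random high-risk tubes (>= 0, score 1.0).
#' @param corridor optional corridor descriptor, a list with `entry`
#'   (0-based boundary voxel), `target` (interior voxel), `radius_mm`
#'   (channel radius) and optional `score` (must be <= 0.1; default 0.05).
#'   A list of such lists requests several corridors.
#' @param seed integer; the same spec and seed reproduce the phantom bit
#'   for bit.
#' @param region_scores candidate penalty scores for background regions,
#'   sampled with replacement. Default mirrors a rated-score table:
#'   `c(0.1, 0.3, 0.5, 0.7, 1.0)`.
#' @param tube_radius_mm tube radius in mm (default 1.2).
#' @param target_radius_mm radius of the target ball labeled around each
#'   corridor's target center (default 1.6 mm, i.e. two default voxels).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dims = c(32, 32, 32), spacing_mm = c(0.8, 0.8, 0.8),
                         n_regions = 5L, n_tubes = 2L, corridor = NULL,
                         seed = 1L, region_scores = c(0.1, 0.3, 0.5, 0.7, 1.0),
                         tube_radius_mm = 1.2, target_radius_mm = 1.6) {
  dims <- as.integer(dims)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(dims) != 3L || any(dims < 8L))
    stop("invalid spec: dims must be 3 integers, each >= 8")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("invalid spec: spacing_mm must be 3 positive reals")
  n_regions <- as.integer(n_regions)
  n_tubes <- as.integer(n_tubes)
  if (n_regions < 1L) stop("invalid spec: n_regions must be >= 1")
  if (n_regions > prod(as.numeric(dims)))
    stop("invalid spec: n_regions exceeds the voxel count")
  if (n_tubes < 0L) stop("invalid spec: n_tubes must be >= 0")
  if (any(region_scores < 0) || any(region_scores > 1))
    stop("invalid spec: region_scores must lie in [0, 1]")
  corridors <- normalize_corridors(corridor, dims)
  structure(list(dims = dims, spacing_mm = spacing_mm,
                 n_regions = n_regions, n_tubes = n_tubes,
                 corridors = corridors, seed = as.integer(seed),
                 region_scores = region_scores,
                 tube_radius_mm = tube_radius_mm,
                 target_radius_mm = target_radius_mm),
            class = "phantom_spec")
}

normalize_corridors <- function(corridor, dims) {
  if (is.null(corridor)) return(list())
  if (!is.null(names(corridor)) && "entry" %in% names(corridor))
    corridor <- list(corridor)
  lapply(corridor, function(co) {
    entry <- as_voxel_matrix(co$entry)
    target <- as_voxel_matrix(co$target)
    if (!in_bounds(entry, dims) || !in_bounds(target, dims))
      stop("invalid spec: corridor endpoints out of bounds")
    on_boundary <- any(entry == 0L) || any(entry == dims - 1L)
    if (!on_boundary)
      stop("invalid spec: corridor entry must lie on the volume boundary")
    interior <- all(target > 0L) && all(target < dims - 1L)
    if (!interior)
      stop("invalid spec: corridor target center must be interior")
    score <- co$score %||% 0.05
    if (score > 0.1)
      stop("invalid spec: corridor score must be <= 0.1 (low-risk channel)")
    list(entry = entry, target = target,
         radius_mm = as.numeric(co$radius_mm %||% 2), score = score)
  })
}

#' Generate a synthetic labeled phantom and its risk table
#'
#' Builds a labeled volume emulating the product of atlas-based brain
#' parcellation at desk scale: background regions are 3D Voronoi cells of
#' seeded points with scores drawn from `region_scores`; tubes (vessel /
#' tract stand-ins) are all voxels within a fixed radius of a random
#' polyline, scored 1.0; each requested corridor paints a dedicated
#' low-risk channel label over everything else along the straight
#' entry-to-target segment, and a distinct target label (score 0) in a
#' small ball at the target center. Every voxel carries exactly one label
#' and the returned risk table names every label. Same spec and seed give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` (a [labeled_volume()]) and `table`
#'   (a `risk_table`).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dims <- spec$dims; sp <- spec$spacing_mm
  n <- prod(dims)
  co <- (arrayInd(seq_len(n), dims) - 1L)
  mm <- sweep(co, 2, sp, "*")
  # Voronoi background regions
  seeds <- cbind(runif(spec$n_regions, 0, (dims[1] - 1) * sp[1]),
                 runif(spec$n_regions, 0, (dims[2] - 1) * sp[2]),
                 runif(spec$n_regions, 0, (dims[3] - 1) * sp[3]))
  labels <- rep(1L, n)
  if (spec$n_regions > 1L) {
    best <- rowSums(sweep(mm, 2, seeds[1, ], "-")^2)
    for (r in 2:spec$n_regions) {
      d2 <- rowSums(sweep(mm, 2, seeds[r, ], "-")^2)
      upd <- d2 < best
      labels[upd] <- r
      best[upd] <- d2[upd]
    }
  }
  names_map <- character(0)
  scores <- numeric(0)
  for (r in seq_len(spec$n_regions)) {
    nm <- sprintf("region_%02d", r)
    names_map[as.character(r)] <- nm
    scores[nm] <- spec$region_scores[sample.int(length(spec$region_scores), 1L)]
  }
  next_label <- spec$n_regions
  # high-risk tubes along random 3-point polylines
  for (t in seq_len(spec$n_tubes)) {
    pts <- cbind(runif(3, 0, (dims[1] - 1) * sp[1]),
                 runif(3, 0, (dims[2] - 1) * sp[2]),
                 runif(3, 0, (dims[3] - 1) * sp[3]))
    member <- rep(FALSE, n)
    for (s in 1:2) {
      d2 <- point_segment_dist2(mm, pts[s, ], pts[s + 1, ])
      member <- member | d2 <= spec$tube_radius_mm^2
    }
    next_label <- next_label + 1L
    labels[member] <- next_label
    nm <- sprintf("tube_%02d", t)
    names_map[as.character(next_label)] <- nm
    scores[nm] <- 1.0
  }
  # low-risk corridors + target balls (painted last so the channel wins)
  for (ci in seq_along(spec$corridors)) {
    co_spec <- spec$corridors[[ci]]
    a <- as.numeric(co_spec$entry) * sp
    b <- as.numeric(co_spec$target) * sp
    d2 <- point_segment_dist2(mm, a, b)
    next_label <- next_label + 1L
    labels[d2 <= co_spec$radius_mm^2] <- next_label
    nm <- sprintf("corridor_%02d", ci)
    names_map[as.character(next_label)] <- nm
    scores[nm] <- co_spec$score
    d2t <- rowSums(sweep(mm, 2, b, "-")^2)
    next_label <- next_label + 1L
    labels[d2t <= spec$target_radius_mm^2] <- next_label
    nmt <- sprintf("target_%02d", ci)
    names_map[as.character(next_label)] <- nmt
    scores[nmt] <- 0.0
  }
  vol <- labeled_volume(array(labels, dim = dims), sp, names_map)
  tab <- load_risk_table(data.frame(segment_name = names(scores),
                                    risk_score = unname(scores)))
  list(volume = vol, table = tab)
}

# Registry of named toy regression fixtures. Oracle costs are computed by
# the Dijkstra oracle at call time (never stored), so connectivity or
# step-cost changes propagate.
toy_case_registry <- function() c("free_line", "center_block", "wall_with_gap")

#' Named toy planning fixtures with oracle-computed optimal cost
#'
#' Small hand-constructed risk grids with a known entry, target, and the
#' exact optimal penalty cost (computed at call time by
#' [dijkstra_oracle()]):
#' \describe{
#'   \item{`free_line`}{1 x 1 x 5 all-zero grid; the only simple path is
#'     the straight line, cost 4 steps x 0.01.}
#'   \item{`center_block`}{3 x 3 x 1 zero grid with a risk-1 center voxel;
#'     the 3-step detour (cost 0.03) beats the 2-step diagonal through the
#'     block (cost 1.02).}
#'   \item{`wall_with_gap`}{5 x 5 x 1 grid with a risk-1 wall across
#'     column i = 2 except one zero-risk gap voxel; every optimal path
#'     passes through the gap.}
#' }
#'
#' @param name one of `"free_line"`, `"center_block"`, `"wall_with_gap"`.
#' @param config a [qlearn_config()] defining connectivity and step cost
#'   for the oracle (defaults: 26-connectivity, step_cost 0.01, gamma 1).
#' @return A `toy_case`: list with `risk` (a [risk_volume()]), `entry`,
#'   `target`, `oracle_cost`, `description`, `config`.
#' @export
generate_toy_case <- function(name, config = qlearn_config(seed = 7L)) {
  specs <- list(
    free_line = function() {
      risk <- risk_volume(array(0, dim = c(1, 1, 5)), c(1, 1, 1))
      list(risk = risk, entry = c(0L, 0L, 0L),
           target = matrix(c(0L, 0L, 4L), 1),
           description = "straight free line, no risk anywhere")
    },
    center_block = function() {
      a <- array(0, dim = c(3, 3, 1))
      a[2, 2, 1] <- 1
      list(risk = risk_volume(a, c(1, 1, 1)), entry = c(0L, 0L, 0L),
           target = matrix(c(2L, 2L, 0L), 1),
           description = "blocked center: detour beats the risky diagonal")
    },
    wall_with_gap = function() {
      a <- array(0, dim = c(5, 5, 1))
      a[3, , 1] <- 1
      a[3, 3, 1] <- 0  # the gap at (2, 2, 0)
      list(risk = risk_volume(a, c(1, 1, 1)), entry = c(0L, 0L, 0L),
           target = matrix(c(4L, 4L, 0L), 1),
           description = "risk-1 wall at i = 2 with a single zero-risk gap")
    }
  )
  if (!name %in% names(specs))
    stop("unknown toy case '", name, "'; known cases: ",
         paste(toy_case_registry(), collapse = ", "))
  tc <- specs[[name]]()
  orc <- dijkstra_oracle(tc$risk, tc$entry, tc$target, config)
  structure(list(name = name, risk = tc$risk, entry = tc$entry,
                 target = tc$target, oracle_cost = orc$cost,
                 oracle_path = orc$path,
                 description = tc$description, config = config),
            class = "toy_case")
}

#' @export
print.toy_case <- function(x, ...) {
  cat(sprintf("<toy_case> '%s': %s (oracle cost %g)\n",
              x$name, x$description, x$oracle_cost))
  invisible(x)
}
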