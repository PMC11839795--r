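#' Volume geometry
#'
#' Dimensions, per-axis spacing and origin of a voxel grid. Voxel indices
#' are 0-based `(i, j, k)` triplets throughout the package; the center of
#' voxel `(i, j, k)` lies at `origin_mm + c(i, j, k) * spacing_mm`.
#'
#' @param dims integer vector of length 3, voxels per axis (each >= 1).
#' @param spacing_mm numeric vector of length 3, mm between voxel centers
#'   (each > 0). Default 0.8 mm isotropic.
#' @param origin_mm numeric vector of length 3, mm position of voxel
#'   `(0, 0, 0)`. Default `c(0, 0, 0)`.
#' @return A `volume_geometry` object.
#' @examples
#' g <- volume_geometry(c(320, 320, 236))
#' voxel_count(g)
#' @export
volume_geometry <- function(dims, spacing_mm = c(0.8, 0.8, 0.8),
                            origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("dims must be 3 integers, each >= 1")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("origin_mm must be 3 finite reals")
  structure(list(dims = dims, spacing_mm = spacing_mm, origin_mm = origin_mm),
            class = "volume_geometry")
}

#' Total number of voxels in a geometry
#'
#' @param geometry a [volume_geometry()].
#' @return The product of the three dimensions, as a double (grids of
#'   clinical size exceed what one would want near the integer limit).
#' @examples
#' voxel_count(volume_geometry(c(320, 320, 236)))  # 24166400
#' @export
voxel_count <- function(geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  prod(as.numeric(geometry$dims))
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf("<volume_geometry> %d x %d x %d voxels, spacing %s mm\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(format(x$spacing_mm), collapse = " x ")))
  invisible(x)
}

# Coerce various containers to a volume_geometry.
as_geometry <- function(x) {
  if (inherits(x, "volume_geometry")) return(x)
  if (inherits(x, "labeled_volume"))
    return(volume_geometry(dim(x$labels), x$spacing_mm))
  if (inherits(x, "risk_volume"))
    return(volume_geometry(dim(x$risk), x$spacing_mm))
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as a volume geometry")
}

# --- voxel index helpers (0-based user-facing, 1-based linear internal) ----

# Normalize a voxel spec (length-3 vector or n x 3 matrix) to an integer
# n x 3 matrix of 0-based indices.
as_voxel_matrix <- function(v) {
  if (is.null(dim(v))) {
    if (length(v) != 3L) stop("a voxel index must have 3 components")
    v <- matrix(as.numeric(v), nrow = 1L)
  }
  v <- as.matrix(v)
  if (ncol(v) != 3L) stop("voxel indices must be given as an n x 3 matrix")
  if (any(!is.finite(v)) || any(v != round(v)))
    stop("voxel indices must be finite integers")
  storage.mode(v) <- "integer"
  dimnames(v) <- NULL
  v
}

in_bounds <- function(v, dims) {
  v[, 1] >= 0L & v[, 1] < dims[1] &
  v[, 2] >= 0L & v[, 2] < dims[2] &
  v[, 3] >= 0L & v[, 3] < dims[3]
}

# 0-based (i,j,k) -> 1-based linear index (i fastest, matching R arrays)
vox_to_lin <- function(v, dims) {
  v[, 1] + dims[1] * (v[, 2] + dims[2] * v[, 3]) + 1L
}

# 1-based linear -> 0-based (i,j,k)
lin_to_vox <- function(l, dims) {
  m <- arrayInd(l, dims)
  storage.mode(m) <- "integer"
  m - 1L
}

# Lexicographically ordered neighbor offsets for 6- or 26-connectivity.
conn_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    stop("connectivity must be 6 or 26")
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  if (connectivity == 6L)
    g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  g <- g[order(g[, 1], g[, 2], g[, 3]), , drop = FALSE]
  storage.mode(g) <- "integer"
  dimnames(g) <- NULL
  g
}

# Evaluate `code` under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sort voxel rows lexicographically (deterministic set representation).
lex_sort_voxels <- function(v) {
  v[order(v[, 1], v[, 2], v[, 3]), , drop = FALSE]
}
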