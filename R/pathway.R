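#' Voxelize a straight surgical pathway as a cylinder
#'
#' Rasterizes the corridor a clinician would paint along the straight
#' segment from `entry_mm` to `target_mm`: the mask contains exactly the
#' voxels whose centers lie within `diameter_mm / 2` of the closed segment
#' (inclusive boundary, flat caps), clipped to the volume. Distances are
#' computed in mm, so anisotropic spacing is handled. The default diameter
#' of 4 mm (0.4 cm) matches standard pathway-drawing practice.
#'
#' @param entry_mm,target_mm numeric length-3 endpoints in mm (voxel
#'   `(i,j,k)` has its center at `origin_mm + c(i,j,k) * spacing_mm`).
#' @param diameter_mm cylinder diameter in mm (> 0). Default 4.
#' @param geometry a [volume_geometry()], [labeled_volume()] or
#'   [risk_volume()] providing shape and spacing.
#' @return A `pathway_mask`: list with `voxels` (n x 3 integer matrix of
#'   0-based indices, lexicographically sorted, deduplicated),
#'   `diameter_mm`, `entry_mm`, `target_mm`, `dims`, `spacing_mm`.
#' @export
voxelize_cylinder <- function(entry_mm, target_mm, diameter_mm = 4,
                              geometry) {
  geom <- as_geometry(geometry)
  entry_mm <- as.numeric(entry_mm); target_mm <- as.numeric(target_mm)
  if (length(entry_mm) != 3L || length(target_mm) != 3L)
    stop("entry and target must be mm 3-vectors")
  if (isTRUE(all.equal(entry_mm, target_mm)))
    stop("degenerate axis: entry and target coincide")
  if (!is.numeric(diameter_mm) || diameter_mm <= 0)
    stop("diameter_mm must be > 0")
  r <- diameter_mm / 2
  sp <- geom$spacing_mm; dims <- geom$dims; org <- geom$origin_mm
  # candidate index window: segment bounding box inflated by the radius
  lo <- pmax(floor((pmin(entry_mm, target_mm) - r - org) / sp), 0)
  hi <- pmin(ceiling((pmax(entry_mm, target_mm) + r - org) / sp), dims - 1)
  if (any(lo > hi)) stop("empty mask: segment lies entirely outside volume")
  cand <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                k = lo[3]:hi[3]))
  centers <- sweep(sweep(cand, 2, sp, "*"), 2, org, "+")
  d2 <- point_segment_dist2(centers, entry_mm, target_mm)
  keep <- d2 <= r * r
  if (!any(keep)) stop("empty mask: no voxel center within the cylinder")
  vox <- as_voxel_matrix(cand[keep, , drop = FALSE])
  structure(list(voxels = lex_sort_voxels(vox), diameter_mm = diameter_mm,
                 entry_mm = entry_mm, target_mm = target_mm,
                 dims = dims, spacing_mm = sp),
            class = "pathway_mask")
}

# Squared distance from rows of `p` (n x 3, mm) to the closed segment a-b.
point_segment_dist2 <- function(p, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  pa <- sweep(p, 2, a, "-")
  t <- pmin(pmax((pa %*% ab) / len2, 0), 1)
  proj <- pa - outer(as.vector(t), ab)
  rowSums(proj^2)
}

#' @export
print.pathway_mask <- function(x, ...) {
  cat(sprintf("<pathway_mask> %d voxels, diameter %g mm\n",
              nrow(x$voxels), x$diameter_mm))
  invisible(x)
}

#' Total risk of a pathway mask or planner path
#'
#' The arithmetic sum of per-voxel penalty scores over the member voxels.
#' Membership is set-like: each voxel counts once even if a path revisits
#' it or a corridor overlaps itself.
#'
#' @param mask_or_path a `pathway_mask`, a `voxel_path`, or an n x 3 matrix
#'   of 0-based voxel indices.
#' @param risk a [risk_volume()].
#' @return The total risk (a single number).
#' @export
path_total_risk <- function(mask_or_path, risk) {
  stopifnot(inherits(risk, "risk_volume"))
  vox <- mask_voxels(mask_or_path)
  vox <- unique(vox)
  dims <- dim(risk$risk)
  if (nrow(vox) > 0 && !all(in_bounds(vox, dims)))
    stop("voxel out of bounds for the risk grid")
  if (nrow(vox) == 0L) return(0)
  sum(risk$risk[vox_to_lin(vox, dims)])
}

mask_voxels <- function(x) {
  if (inherits(x, "pathway_mask")) return(x$voxels)
  if (inherits(x, "voxel_path")) return(unclass(x))
  as_voxel_matrix(x)
}

#' Write a binary pathway/path mask to NRRD
#'
#' Member voxels get value 1, all others 0 — the segment-file convention.
#'
#' @param mask a `pathway_mask`, `voxel_path`, or n x 3 index matrix.
#' @param path output `.nrrd` path.
#' @param geometry grid shape/spacing (required unless `mask` is a
#'   `pathway_mask`, which carries its own).
#' @return `path`, invisibly.
#' @export
write_mask_nrrd <- function(mask, path, geometry = NULL) {
  if (inherits(mask, "pathway_mask") && is.null(geometry)) {
    dims <- mask$dims; sp <- mask$spacing_mm
  } else {
    geom <- as_geometry(geometry)
    dims <- geom$dims; sp <- geom$spacing_mm
  }
  vox <- unique(mask_voxels(mask))
  grid <- array(0L, dim = dims)
  grid[vox_to_lin(vox, dims)] <- 1L
  write_nrrd(grid, path, spacing_mm = sp, type = "int32")
}

#' Read a binary mask NRRD into a voxel set
#'
#' @param path `.nrrd` file; any nonzero voxel is a member.
#' @return A list with `voxels` (n x 3, 0-based, sorted), `dims`,
#'   `spacing_mm`.
#' @export
read_mask_nrrd <- function(path) {
  v <- read_nrrd(path)
  idx <- which(v$data != 0)
  vox <- if (length(idx) > 0) lex_sort_voxels(lin_to_vox(idx, dim(v$data)))
         else matrix(integer(0), 0, 3)
  list(voxels = vox, dims = dim(v$data), spacing_mm = v$spacing_mm)
}
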