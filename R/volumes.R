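#' Labeled volume (segmented brain)
#'
#' A 3D integer label grid with per-axis spacing and a label-to-segment-name
#' map. Label 0 may be left unnamed as reserved background; every other
#' label occurring in the grid must have a name.
#'
#' @param labels 3D integer array of segment labels.
#' @param spacing_mm numeric length-3, mm between voxel centers, each > 0.
#' @param names named character vector mapping label values (as names, e.g.
#'   `"1"`) to segment names.
#' @return A `labeled_volume` object.
#' @export
labeled_volume <- function(labels, spacing_mm = c(0.8, 0.8, 0.8), names) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  if (any(labels != round(labels))) stop("labels must be integer-valued")
  storage.mode(labels) <- "integer"
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  if (is.null(base::names(names)) || !is.character(names))
    stop("names must be a named character vector (label -> segment name)")
  present <- unique(as.vector(labels))
  missing <- setdiff(present, c(0L, as.integer(base::names(names))))
  if (length(missing) > 0L)
    stop("labels present in the grid but absent from the name map: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, spacing_mm = spacing_mm, names = names),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat(sprintf("<labeled_volume> %s voxels, spacing %s mm, %d named segments\n",
              paste(dim(x$labels), collapse = " x "),
              paste(format(x$spacing_mm), collapse = " x "),
              length(x$names)))
  invisible(x)
}

#' Per-voxel risk (penalty) volume
#'
#' A 3D grid of penalty scores in \[0, 1\]: 0 marks risk-free structures and
#' 1 marks penalized (risky) structures. This is the planner's cost field.
#'
#' @param risk 3D numeric array with all values in \[0, 1\].
#' @param spacing_mm numeric length-3, mm between voxel centers.
#' @return A `risk_volume` object.
#' @export
risk_volume <- function(risk, spacing_mm = c(0.8, 0.8, 0.8)) {
  if (length(dim(risk)) != 3L) stop("risk must be a 3D array")
  risk <- risk + 0.0
  if (any(!is.finite(risk)) || any(risk < 0) || any(risk > 1))
    stop("risk values must all lie in [0, 1]")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be 3 positive reals")
  structure(list(risk = risk, spacing_mm = spacing_mm), class = "risk_volume")
}

#' @export
print.risk_volume <- function(x, ...) {
  cat(sprintf("<risk_volume> %s voxels, spacing %s mm, risk range [%g, %g]\n",
              paste(dim(x$risk), collapse = " x "),
              paste(format(x$spacing_mm), collapse = " x "),
              min(x$risk), max(x$risk)))
  invisible(x)
}

#' Read a labeled volume from NRRD or NIfTI
#'
#' Voxel values must be integers (a label map, not an image). Spacing is
#' taken from the file header; a missing header spacing is an error unless
#' `spacing_mm` is supplied explicitly. Segment names come from an optional
#' sidecar CSV with columns `label,segment_name`.
#'
#' @param path path to a `.nrrd`, `.nii` or `.nii.gz` file.
#' @param names_csv optional path to a sidecar CSV mapping labels to names.
#' @param spacing_mm optional explicit spacing override (required if the
#'   file header carries none).
#' @return A [labeled_volume()]. If no sidecar is given, labels are named
#'   `label_<value>`.
#' @export
read_labeled_volume <- function(path, names_csv = NULL, spacing_mm = NULL) {
  v <- read_volume_any(path)
  if (any(v$data != round(v$data)))
    stop("volume at ", path, " is not integer-valued; refusing to treat ",
         "float data as a label map")
  storage.mode(v$data) <- "integer"
  sp <- resolve_spacing(v$spacing_mm, spacing_mm, path)
  labs <- sort(setdiff(unique(as.vector(v$data)), 0L))
  if (!is.null(names_csv)) {
    tab <- utils::read.csv(names_csv, stringsAsFactors = FALSE)
    if (!all(c("label", "segment_name") %in% base::names(tab)))
      stop("names sidecar must have columns label,segment_name")
    nm <- stats::setNames(as.character(tab$segment_name),
                          as.character(tab$label))
  } else {
    nm <- stats::setNames(paste0("label_", labs), as.character(labs))
  }
  labeled_volume(v$data, sp, nm)
}

#' Read a risk volume from NRRD
#'
#' @param path path to a `.nrrd` file with values in \[0, 1\].
#' @param spacing_mm optional spacing override.
#' @return A [risk_volume()].
#' @export
read_risk_volume <- function(path, spacing_mm = NULL) {
  v <- read_volume_any(path)
  sp <- resolve_spacing(v$spacing_mm, spacing_mm, path)
  risk_volume(v$data, sp)
}

#' Write a risk volume to NRRD
#'
#' Raw encoding: values round-trip bit-exactly through [read_risk_volume()].
#'
#' @param risk a [risk_volume()].
#' @param path output path.
#' @param encoding NRRD encoding passed to [write_nrrd()].
#' @return `path`, invisibly.
#' @export
write_risk_volume <- function(risk, path, encoding = "raw") {
  stopifnot(inherits(risk, "risk_volume"))
  write_nrrd(risk$risk, path, spacing_mm = risk$spacing_mm, type = "double",
             encoding = encoding)
}

#' Write a labeled volume to NRRD (plus optional name sidecar)
#'
#' @param volume a [labeled_volume()].
#' @param path output `.nrrd` path.
#' @param names_csv optional path for a `label,segment_name` sidecar CSV.
#' @param encoding NRRD encoding passed to [write_nrrd()].
#' @return `path`, invisibly.
#' @export
write_labeled_volume <- function(volume, path, names_csv = NULL,
                                 encoding = "raw") {
  stopifnot(inherits(volume, "labeled_volume"))
  write_nrrd(volume$labels, path, spacing_mm = volume$spacing_mm,
             type = "int32", encoding = encoding)
  if (!is.null(names_csv)) {
    df <- data.frame(label = base::names(volume$names),
                     segment_name = unname(volume$names))
    utils::write.csv(df, names_csv, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

read_volume_any <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nrrd$", low)) {
    read_nrrd(path)
  } else if (grepl("\\.nii(\\.gz)?$", low)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    dat <- as.array(img)
    if (length(dim(dat)) != 3L) stop("expected a 3D NIfTI volume")
    dat <- array(as.vector(dat), dim = dim(dat))  # drop niftiImage attrs
    list(data = dat, spacing_mm = as.numeric(sp)[1:3], type = "nifti")
  } else {
    stop("unsupported volume format (expect .nrrd, .nii or .nii.gz): ", path)
  }
}

resolve_spacing <- function(header_spacing, override, path) {
  if (!is.null(override)) return(as.numeric(override))
  if (any(is.na(header_spacing)))
    stop("no spacing recorded in ", path,
         "; pass spacing_mm explicitly to override")
  header_spacing
}

#' Voxel indices carrying a named segment
#'
#' @param volume a [labeled_volume()].
#' @param segment_name segment name to look up (matched after trimming and
#'   case-folding, like the risk table loader).
#' @return An n x 3 integer matrix of 0-based voxel indices.
#' @export
label_voxels <- function(volume, segment_name) {
  stopifnot(inherits(volume, "labeled_volume"))
  key <- normalize_segment_name(segment_name)
  hit <- base::names(volume$names)[normalize_segment_name(volume$names) == key]
  if (length(hit) == 0L) stop("no segment named '", segment_name, "'")
  lab <- as.integer(hit)
  idx <- which(array(volume$labels %in% lab, dim = dim(volume$labels)))
  if (length(idx) == 0L) return(matrix(integer(0), 0, 3))
  lex_sort_voxels(lin_to_vox(idx, dim(volume$labels)))
}
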