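#' Load a segment-name/risk-score table
#'
#' Parses a two-column table (CSV or TSV, or an already-loaded data frame)
#' of anatomical segment names and penalty scores in \[0, 1\], where 0 marks
#' risk-free structures and 1 marks penalized structures. Names are
#' normalized (whitespace trimmed and squeezed, case-folded) before
#' uniqueness is checked; duplicate rows with identical scores collapse,
#' duplicates with conflicting scores are an error naming the segment.
#'
#' @param source a file path or a data frame. Columns named `segment_name`
#'   and `risk_score` are used if present, otherwise the first two columns.
#' @return A `risk_table`: a named numeric vector keyed by normalized
#'   segment name.
#' @examples
#' tab <- load_risk_table(data.frame(segment_name = c("R. globus pallidus",
#'                                                    "R. lateral ventricle"),
#'                                   risk_score = c(1.0, 0.1)))
#' risk_score(tab, "R. globus pallidus")
#' @export
load_risk_table <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("risk table not found: ", source)
    sep <- if (grepl("\\.tsv$|\\.txt$", tolower(source))) "\t" else ","
    df <- utils::read.csv(source, sep = sep, stringsAsFactors = FALSE)
  } else if (is.data.frame(source)) {
    df <- source
  } else {
    stop("source must be a file path or a data frame")
  }
  if (ncol(df) < 2L) stop("risk table needs at least two columns")
  nm_col <- if ("segment_name" %in% names(df)) "segment_name" else names(df)[1]
  sc_col <- if ("risk_score" %in% names(df)) "risk_score" else names(df)[2]
  nm <- normalize_segment_name(as.character(df[[nm_col]]))
  sc <- suppressWarnings(as.numeric(df[[sc_col]]))
  if (any(is.na(sc)))
    stop("non-numeric risk score for segment(s): ",
         paste(unique(nm[is.na(sc)]), collapse = ", "))
  bad <- sc < 0 | sc > 1
  if (any(bad))
    stop("risk scores outside [0, 1] for segment(s): ",
         paste(unique(nm[bad]), collapse = ", "))
  if (any(nm == "")) stop("empty segment name in risk table")
  conflicts <- tapply(sc, nm, function(x) length(unique(x)) > 1L)
  if (any(conflicts))
    stop("conflicting duplicate risk scores for segment(s): ",
         paste(names(conflicts)[conflicts], collapse = ", "))
  keep <- !duplicated(nm)
  structure(stats::setNames(sc[keep], nm[keep]), class = "risk_table")
}

# Trim, squeeze internal whitespace, case-fold.
normalize_segment_name <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Look up a segment's risk score
#'
#' @param table a [load_risk_table()] result.
#' @param segment_name one or more segment names (normalized before lookup).
#' @return Numeric scores; `NA` where the table has no entry.
#' @export
risk_score <- function(table, segment_name) {
  stopifnot(inherits(table, "risk_table"))
  unname(unclass(table)[normalize_segment_name(segment_name)])
}

#' @export
print.risk_table <- function(x, ...) {
  cat(sprintf("<risk_table> %d segments, scores in [%g, %g]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Assign per-voxel risk from a labeled volume and a risk table
#'
#' Every voxel receives the penalty score of the segment its label names.
#' Unscored segments are an error listing the offending names, unless an
#' explicit `default` is supplied (silent defaults are refused by design:
#' unscored anatomy should fail loudly). Background label 0 without a name
#' map entry is treated like any other unscored segment.
#'
#' @param volume a [labeled_volume()].
#' @param table a [load_risk_table()] result.
#' @param default optional score in \[0, 1\] for segments missing from the
#'   table (and for unnamed background).
#' @return A [risk_volume()] with the same shape and spacing.
#' @export
assign_risk <- function(volume, table, default = NULL) {
  stopifnot(inherits(volume, "labeled_volume"), inherits(table, "risk_table"))
  if (!is.null(default)) {
    default <- as.numeric(default)
    if (length(default) != 1L || is.na(default) || default < 0 || default > 1)
      stop("default must be a single score in [0, 1]")
  }
  labs <- sort(unique(as.vector(volume$labels)))
  score_of <- stats::setNames(rep(NA_real_, length(labs)), as.character(labs))
  for (l in labs) {
    key <- as.character(l)
    if (key %in% names(volume$names)) {
      score_of[key] <- risk_score(table, volume$names[[key]])
    }
  }
  unmapped <- names(score_of)[is.na(score_of)]
  if (length(unmapped) > 0L) {
    if (is.null(default)) {
      nm <- vapply(unmapped, function(k)
        if (k %in% names(volume$names)) volume$names[[k]]
        else paste0("<unnamed label ", k, ">"), character(1))
      stop("no risk score for segment(s): ", paste(nm, collapse = ", "),
           " (pass default= to fill explicitly)")
    }
    score_of[unmapped] <- default
  }
  risk <- array(score_of[as.character(volume$labels)], dim = dim(volume$labels))
  risk_volume(risk, volume$spacing_mm)
}

#' Fuse several aligned risk layers into one
#'
#' Combines per-voxel penalties from pre-aligned modality layers (e.g.
#' parcellation, vascular, tract fields). The default `max` keeps the
#' highest penalty at every voxel — where aligned layers disagree, the
#' highest penalty wins; `sum_clipped` adds the layers and clips at 1.
#'
#' @param layers a list of [risk_volume()] objects with identical shapes
#'   and spacings (a single `risk_volume` is also accepted).
#' @param mode `"max"` (default) or `"sum_clipped"`.
#' @return A fused [risk_volume()].
#' @export
fuse_layers <- function(layers, mode = c("max", "sum_clipped")) {
  mode <- match.arg(mode)
  if (inherits(layers, "risk_volume")) layers <- list(layers)
  if (length(layers) < 1L) stop("need at least one layer to fuse")
  if (!all(vapply(layers, inherits, logical(1), "risk_volume")))
    stop("all layers must be risk_volume objects")
  d0 <- dim(layers[[1]]$risk)
  s0 <- layers[[1]]$spacing_mm
  for (l in layers[-1]) {
    if (!identical(dim(l$risk), d0))
      stop("layer shape mismatch: ", paste(dim(l$risk), collapse = "x"),
           " vs ", paste(d0, collapse = "x"))
    if (!isTRUE(all.equal(l$spacing_mm, s0)))
      stop("layer spacing mismatch")
  }
  fused <- Reduce(
    if (mode == "max") pmax else `+`,
    lapply(layers, function(l) l$risk)
  )
  if (mode == "sum_clipped") fused <- pmin(fused, 1.0)
  risk_volume(array(fused, dim = d0), s0)
}
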