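#' Define a named surgical approach case
#'
#' One row of an approach comparison: a clinician-chosen entry voxel, the
#' target region, and optionally the hand-drawn pathway mask whose total
#' risk is reported alongside the planner's scores.
#'
#' @param name unique approach name (e.g. "anterior transsylvian").
#' @param entry 0-based entry voxel.
#' @param target n x 3 matrix (or triplet) of target voxels.
#' @param hand_mask optional `pathway_mask`, voxel matrix, or path to a
#'   binary mask NRRD.
#' @return An `approach_case`.
#' @export
approach_case <- function(name, entry, target, hand_mask = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("name must be a non-empty string")
  structure(list(name = name, entry = as_voxel_matrix(entry),
                 target = as_voxel_matrix(target), hand_mask = hand_mask),
            class = "approach_case")
}

#' Compare surgical approaches on a shared risk volume
#'
#' For each case: the hand-drawn pathway's total risk (`NA` if no mask was
#' given), the Q-learning planner's Q-score, and the planner path's risk
#' sum (Qr). Rows are ranked ascending by Q-score — the lowest total
#' Q-value defines the best pathway — with lexicographic name tie-break. A
#' planner failure marks the row `failed` and the comparison continues.
#' Provenance (configuration, seed, volume checksum) is embedded so a
#' report is reproducible from its own metadata.
#'
#' @param cases a list of [approach_case()] objects (unique names).
#' @param risk a [risk_volume()].
#' @param config a [qlearn_config()] used for every planner run.
#' @return An `approach_report`: a data frame with columns `name`,
#'   `hand_total_risk`, `q_score`, `qr_score`, `rank_by_q`, `status`, plus
#'   a `provenance` attribute.
#' @export
compare_approaches <- function(cases, risk, config = qlearn_config()) {
  stopifnot(inherits(risk, "risk_volume"), inherits(config, "qlearn_config"))
  if (inherits(cases, "approach_case")) cases <- list(cases)
  if (length(cases) < 1L) stop("need at least one approach case")
  if (!all(vapply(cases, inherits, logical(1), "approach_case")))
    stop("cases must be approach_case objects")
  nms <- vapply(cases, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("approach names must be unique")
  rows <- lapply(cases, function(cs) {
    hand <- NA_real_
    if (!is.null(cs$hand_mask)) {
      m <- cs$hand_mask
      if (is.character(m)) m <- read_mask_nrrd(m)$voxels
      hand <- path_total_risk(m, risk)
    }
    res <- tryCatch(qlearn_plan(risk, cs$entry, cs$target, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(name = cs$name, hand_total_risk = hand,
                 q_score = NA_real_, qr_score = NA_real_,
                 status = paste0("failed: ", conditionMessage(res)),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = cs$name, hand_total_risk = hand,
                 q_score = res$q_score, qr_score = res$qr_score,
                 status = "ok", stringsAsFactors = FALSE)
    }
  })
  df <- do.call(rbind, rows)
  ord <- order(df$q_score, df$name, na.last = TRUE)
  rank <- integer(nrow(df))
  rank[ord] <- seq_len(nrow(df))
  rank[is.na(df$q_score)] <- NA_integer_
  df$rank_by_q <- rank
  df <- df[, c("name", "hand_total_risk", "q_score", "qr_score",
               "rank_by_q", "status")]
  attr(df, "provenance") <- list(
    config = unclass(config),
    seed = config$seed,
    volume_md5 = volume_checksum(risk),
    dims = dim(risk$risk),
    spacing_mm = risk$spacing_mm
  )
  class(df) <- c("approach_report", "data.frame")
  df
}

# md5 of the risk payload (dims + spacing + values), for provenance.
volume_checksum <- function(risk) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  writeBin(as.integer(dim(risk$risk)), con)
  writeBin(as.numeric(risk$spacing_mm), con)
  writeBin(as.numeric(risk$risk), con)
  close(con)
  unname(tools::md5sum(tf))
}

#' @export
print.approach_report <- function(x, ...) {
  cat(render_report(x, "markdown"))
  invisible(x)
}

#' Render an approach report as CSV, JSON or markdown
#'
#' Lossless rendering of the comparison table; the markdown layout mirrors
#' the conventional columns (pathway, total risk, total Q-value, Qr).
#'
#' @param report an [compare_approaches()] result.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return A single string.
#' @export
render_report <- function(report, format = c("csv", "json", "markdown")) {
  if (!inherits(report, "approach_report")) stop("not an approach_report")
  format <- tryCatch(match.arg(format),
                     error = function(e) stop("unknown report format: ",
                                              format[1]))
  df <- as.data.frame(report)
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(format_report_df(df), con, row.names = FALSE,
                     quote = TRUE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    prov <- attr(report, "provenance")
    prov$config$barrier_threshold <- prov$config$barrier_threshold %||% NA
    prov$config$step_cap <- prov$config$step_cap %||% NA
    return(as.character(jsonlite::toJSON(
      list(approaches = df, provenance = prov),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")))
  }
  # markdown
  hdr <- "| Pathway | Total risk score | Total Q-value | Qr | Rank | Status |"
  sep <- "|---|---|---|---|---|---|"
  fmt <- function(x) ifelse(is.na(x), "NA", format(x, digits = 15))
  body <- sprintf("| %s | %s | %s | %s | %s | %s |",
                  df$name, fmt(df$hand_total_risk), fmt(df$q_score),
                  fmt(df$qr_score), fmt(df$rank_by_q), df$status)
  paste0(paste(c(hdr, sep, body), collapse = "\n"), "\n")
}

format_report_df <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x)
    ifelse(is.na(x), NA, format(x, digits = 15, scientific = FALSE,
                                trim = TRUE)))
  df
}

#' Parse a rendered CSV report back into a data frame
#'
#' @param text a CSV string produced by [render_report()].
#' @return A data frame with numeric score columns.
#' @export
parse_report_csv <- function(text) {
  df <- utils::read.csv(text = text, stringsAsFactors = FALSE)
  for (cn in c("hand_total_risk", "q_score", "qr_score", "rank_by_q"))
    df[[cn]] <- as.numeric(df[[cn]])
  df
}
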