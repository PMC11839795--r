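#' Write a 3D array as an NRRD file
#'
#' Minimal NRRD0004 writer covering the needs of this package: 3D integer
#' label maps / binary masks (`int32`) and floating-point risk volumes
#' (`double`), with per-axis spacing recorded in the `spacings:` field.
#' `raw` encoding round-trips doubles bit-exactly; `ascii` produces a fully
#' text file (handy for small fixtures); `gzip` compresses the raw stream.
#'
#' @param x a 3D array (integer or double).
#' @param path output file path (conventionally `.nrrd`).
#' @param spacing_mm numeric length-3 per-axis spacing in mm.
#' @param type one of `"auto"`, `"int32"`, `"double"`. `"auto"` writes
#'   `int32` for integer arrays and `double` otherwise.
#' @param encoding one of `"raw"`, `"ascii"`, `"gzip"`.
#' @return `path`, invisibly.
#' @seealso [read_nrrd()]
#' @export
write_nrrd <- function(x, path, spacing_mm = c(1, 1, 1),
                       type = c("auto", "int32", "double"),
                       encoding = c("raw", "ascii", "gzip")) {
  type <- match.arg(type)
  encoding <- match.arg(encoding)
  if (length(dim(x)) != 3L) stop("write_nrrd expects a 3D array")
  if (type == "auto")
    type <- if (is.integer(x) || all(x == round(x))) "int32" else "double"
  nrrd_type <- switch(type, int32 = "int", double = "double")
  hdr <- c(
    "NRRD0004",
    "# minimal NRRD written by the qpath package",
    paste0("type: ", nrrd_type),
    "dimension: 3",
    paste0("sizes: ", paste(dim(x), collapse = " ")),
    paste0("spacings: ", paste(format(spacing_mm, digits = 17), collapse = " ")),
    paste0("encoding: ", encoding)
  )
  if (encoding != "ascii") hdr <- c(hdr, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(charToRaw("\n"), con)
  vals <- as.vector(x)
  if (encoding == "ascii") {
    txt <- if (type == "int32") format(as.integer(vals), scientific = FALSE)
           else format(vals, digits = 17)
    writeLines(paste(txt, collapse = " "), con, sep = "\n")
  } else {
    payload <- if (type == "int32") {
      writeBin(as.integer(vals), raw(), size = 4L, endian = "little")
    } else {
      writeBin(as.numeric(vals), raw(), size = 8L, endian = "little")
    }
    if (encoding == "gzip") payload <- memCompress(payload, type = "gzip")
    writeBin(payload, con)
  }
  invisible(path)
}

#' Read an NRRD file into a 3D array
#'
#' Reads the subset of NRRD0004 this package writes, plus common variants:
#' scalar 3D data in `raw`, `ascii`/`txt`/`text`, or `gzip`/`gz` encoding;
#' integer and floating-point types; spacing from either `spacings:` or a
#' diagonal `space directions:` field.
#'
#' @param path path to a `.nrrd` file.
#' @return A list with `data` (3D array), `spacing_mm` (numeric length 3,
#'   `NA` if the header carries no spacing), and `type` (the NRRD type
#'   string).
#' @seealso [write_nrrd()]
#' @export
read_nrrd <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # header ends at the first blank line (LF LF, tolerating CR)
  nl <- which(bytes == as.raw(10L))
  split_at <- NA_integer_
  prev <- 0L
  for (p in nl) {
    line <- if (p - prev > 1L) bytes[(prev + 1L):(p - 1L)] else raw(0)
    line <- line[line != as.raw(13L)]
    if (length(line) == 0L) { split_at <- p; break }
    prev <- p
  }
  if (is.na(split_at)) stop("malformed NRRD: no blank line after header")
  hdr_txt <- rawToChar(bytes[seq_len(split_at)])
  lines <- strsplit(hdr_txt, "\n", fixed = TRUE)[[1]]
  lines <- sub("\r$", "", lines)
  if (!grepl("^NRRD000[1-9]", lines[1])) stop("not an NRRD file: ", path)
  lines <- lines[-1]
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) fields[[tolower(trimws(m[2]))]] <- trimws(m[3])
  }
  dimension <- as.integer(fields[["dimension"]])
  if (is.na(dimension) || dimension != 3L)
    stop("only 3-dimensional NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1]])
  nrrd_type <- tolower(fields[["type"]])
  encoding <- tolower(fields[["encoding"]])
  endian <- tolower(fields[["endian"]] %||% "little")
  spacing <- rep(NA_real_, 3)
  if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    if (length(vecs) == 3L) {
      m <- vapply(vecs, function(s)
        as.numeric(strsplit(gsub("[()]", "", s), ",")[[1]]), numeric(3))
      spacing <- sqrt(colSums(m^2))
    }
  }
  tinfo <- nrrd_type_info(nrrd_type)
  n <- prod(as.numeric(sizes))
  payload <- bytes[(split_at + 1L):length(bytes)]
  vals <- switch(
    encoding,
    ascii = , txt = , text =
      scan(text = rawToChar(payload), what = numeric(), quiet = TRUE),
    raw = decode_binary(payload, tinfo, n, endian),
    gzip = , gz = decode_binary(memDecompress(payload, type = "gzip"),
                                tinfo, n, endian),
    stop("unsupported NRRD encoding: ", encoding)
  )
  if (length(vals) != n)
    stop("NRRD payload has ", length(vals), " values, expected ", n)
  data <- array(vals, dim = sizes)
  if (tinfo$integer) storage.mode(data) <- "integer"
  list(data = data, spacing_mm = spacing, type = nrrd_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nrrd_type_info <- function(t) {
  switch(t,
    "signed char" = , "int8" = , "int8_t" =
      list(what = "integer", size = 1L, signed = TRUE, integer = TRUE),
    "uchar" = , "unsigned char" = , "uint8" = , "uint8_t" =
      list(what = "integer", size = 1L, signed = FALSE, integer = TRUE),
    "short" = , "short int" = , "int16" = , "int16_t" =
      list(what = "integer", size = 2L, signed = TRUE, integer = TRUE),
    "ushort" = , "unsigned short" = , "uint16" = , "uint16_t" =
      list(what = "integer", size = 2L, signed = FALSE, integer = TRUE),
    "int" = , "signed int" = , "int32" = , "int32_t" =
      list(what = "integer", size = 4L, signed = TRUE, integer = TRUE),
    "float" =
      list(what = "double", size = 4L, signed = TRUE, integer = FALSE),
    "double" =
      list(what = "double", size = 8L, signed = TRUE, integer = FALSE),
    stop("unsupported NRRD type: ", t)
  )
}

decode_binary <- function(payload, tinfo, n, endian) {
  readBin(payload, what = tinfo$what, n = n, size = tinfo$size,
          signed = tinfo$signed,
          endian = if (endian == "big") "big" else "little")
}
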