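#' Read and write NRRD volumes
#'
#' Minimal NRRD (Nearly Raw Raster Data) I/O for 3D scalar volumes and masks.
#' Supports the subset of the format the package emits: 3D data, `raw` or
#' `ascii`/`text` encodings, little/big endian, common scalar types, with
#' spacing carried either in `space directions` or `spacings` and origin in
#' `space origin`. The fastest NRRD axis maps to the first array dimension,
#' matching R's column-major layout.
#'
#' @param path file path.
#' @param x an [image_volume()] or [roi_mask()].
#' @param encoding `"raw"` (binary, default) or `"ascii"`.
#' @return `read_nrrd()` returns an [image_volume()] (coerce with
#'   [as_roi_mask()] when the file holds a binary mask); `write_nrrd()`
#'   returns `path` invisibly.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) hdr[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(hdr[["dimension"]])
  if (!identical(dimn, 3L)) stop("only 3D NRRD supported, got dimension ", dimn)
  sizes <- as.integer(strsplit(hdr[["sizes"]], "\\s+")[[1]])
  n <- prod(sizes)
  type <- tolower(hdr[["type"]])
  endian <- if (!is.null(hdr[["endian"]])) hdr[["endian"]] else "little"
  enc <- tolower(hdr[["encoding"]])
  rb <- function(what, size, signed = TRUE)
    readBin(con, what, n = n, size = size, endian = endian, signed = signed)
  if (enc == "raw") {
    vals <- switch(type,
      "double" = rb(numeric(), 8L),
      "float" = rb(numeric(), 4L),
      "int" = , "int32" = , "signed int" = rb(integer(), 4L),
      "short" = , "int16" = , "signed short" = rb(integer(), 2L),
      "ushort" = , "uint16" = , "unsigned short" = rb(integer(), 2L, signed = FALSE),
      "uchar" = , "uint8" = , "unsigned char" = as.integer(readBin(con, raw(), n = n)),
      stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  spacing <- c(1, 1, 1)
  if (!is.null(hdr[["space directions"]])) {
    vecs <- regmatches(hdr[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", hdr[["space directions"]]))[[1]]
    m <- vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
    spacing <- sqrt(colSums(m ^ 2))
  } else if (!is.null(hdr[["spacings"]])) {
    spacing <- as.numeric(strsplit(hdr[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(hdr[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "", hdr[["space origin"]]), ",")[[1]])
  image_volume(array(as.numeric(vals), dim = sizes), spacing, origin)
}

#' @rdname read_nrrd
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  is_mask <- inherits(x, "roi_mask")
  if (!is_mask && !inherits(x, "image_volume"))
    stop("'x' must be an image_volume or roi_mask")
  sizes <- dim(x$values)
  type <- if (is_mask) "unsigned char" else "double"
  hdr <- c("NRRD0004",
           paste("type:", type),
           "dimension: 3",
           paste("sizes:", paste(sizes, collapse = " ")),
           "space: left-posterior-superior",
           sprintf("space directions: (%g,0,0) (0,%g,0) (0,0,%g)",
                   x$spacing[1], x$spacing[2], x$spacing[3]),
           sprintf("space origin: (%g,%g,%g)",
                   x$origin[1], x$origin[2], x$origin[3]),
           paste("encoding:", encoding))
  if (encoding == "raw") hdr <- c(hdr, "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con)
  if (encoding == "raw") {
    if (is_mask) writeBin(as.raw(x$values), con)
    else writeBin(as.numeric(x$values), con, size = 8L, endian = "little")
  } else {
    writeLines(paste(format(as.numeric(x$values), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname read_nrrd
#' @export
as_roi_mask <- function(x) {
  if (inherits(x, "roi_mask")) return(x)
  roi_mask(x$values != 0, x$spacing, x$origin)
}
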