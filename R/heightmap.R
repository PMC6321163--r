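#' Construct a height map
#'
#' A height map is the basic data object of the pipeline: a rectangular
#' matrix of surface heights in nanometres together with the lateral
#' sampling (nm per pixel). Row 1 is the top scan line; heights are stored
#' row-major with y increasing downward, and every length computation in
#' the package converts pixel distances to nm through `pixel_size`.
#'
#' @param heights numeric matrix of surface heights, nm.
#' @param pixel_size isotropic lateral sampling, nm per pixel (> 0).
#' @param source_id opaque image identifier carried through result tables.
#' @return an object of class `height_map` (list with `heights`,
#'   `pixel_size`, `source_id`).
#' @export
height_map <- function(heights, pixel_size, source_id = "image") {
  if (!is.matrix(heights) || !is.numeric(heights) || length(heights) == 0L)
    stop("`heights` must be a non-empty numeric matrix")
  if (!all(is.finite(heights)))
    stop("`heights` contains non-finite values")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (nm per pixel)")
  structure(
    list(heights = heights, pixel_size = as.numeric(pixel_size),
         source_id = as.character(source_id)[1L]),
    class = "height_map"
  )
}

#' @export
print.height_map <- function(x, ...) {
  d <- dim(x$heights)
  cat(sprintf("<height_map> %s: %d x %d px, %.4g nm/px, range [%.3g, %.3g] nm\n",
              x$source_id, d[1], d[2], x$pixel_size,
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' Condition label for one image
#'
#' Identifies the experimental cell an image belongs to: DHA concentration
#' (uM), incubation time (h) and replicate index. The study grid uses
#' concentrations {0, 30, 100} uM and times {1, 6, 24} h, but any
#' non-negative concentration and positive time are accepted.
#'
#' @param dha_concentration DHA concentration, uM (>= 0).
#' @param incubation_time incubation time, hours (> 0).
#' @param replicate replicate/image index within the condition (>= 1).
#' @return a `condition_label` object.
#' @export
condition_label <- function(dha_concentration, incubation_time, replicate = 1L) {
  if (dha_concentration < 0) stop("`dha_concentration` must be >= 0 uM")
  if (incubation_time <= 0) stop("`incubation_time` must be > 0 h")
  if (replicate < 1) stop("`replicate` must be >= 1")
  structure(
    list(dha_concentration = as.numeric(dha_concentration),
         incubation_time = as.numeric(incubation_time),
         replicate = as.integer(replicate)),
    class = "condition_label"
  )
}

#' @export
format.condition_label <- function(x, ...) {
  sprintf("dha%g_t%gh_r%d", x$dha_concentration, x$incubation_time, x$replicate)
}

#' @export
print.condition_label <- function(x, ...) {
  cat("<condition_label>", format(x), "\n"); invisible(x)
}

#' Read a height map from file
#'
#' Supports 32-bit float grayscale TIFF and whitespace-delimited ASCII
#' matrices (one image row per line, first line = top scan line). Values
#' are taken to be heights in nm and are never rescaled on input. Neither
#' format carries the physical scan size, so `pixel_size` must be given.
#'
#' @param path file to read.
#' @param pixel_size nm per pixel. Required.
#' @param source_id identifier; defaults to the file name.
#' @return a [height_map()].
#' @export
read_height_map <- function(path, pixel_size = NULL, source_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(pixel_size))
    stop("`pixel_size` (nm per pixel) must be supplied: ",
         "TIFF/ASCII height maps carry no physical scale")
  if (is.null(source_id)) source_id <- basename(path)
  if (is_tiff_file(path)) {
    m <- tiff::readTIFF(path, all = FALSE)
    if (length(dim(m)) == 3L) m <- m[, , 1L]  # collapse grayscale-with-channels
    storage.mode(m) <- "double"
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty ASCII matrix file: ", path)
    rows <- lapply(lines, function(l) {
      v <- strsplit(trimws(l), "[[:space:]]+")[[1L]]
      x <- suppressWarnings(as.numeric(v))
      if (anyNA(x)) stop("non-numeric cell in ASCII matrix file: ", path)
      x
    })
    n <- lengths(rows)
    if (length(unique(n)) != 1L)
      stop("ragged rows in ASCII matrix file (row lengths ",
           paste(unique(n), collapse = ", "), "): ", path)
    m <- do.call(rbind, rows)
  }
  height_map(m, pixel_size = pixel_size, source_id = source_id)
}

#' Write a height map to file
#'
#' `tiff` writes an uncompressed single-strip 32-bit IEEE-float grayscale
#' TIFF (bit-exact round trip at single precision); `ascii` writes one
#' image row per line with enough digits that the round-trip error is
#' below 1e-6 of the stored value (at least 9 significant digits).
#'
#' @param map a [height_map()].
#' @param path output file; parent directory must exist.
#' @param format `"tiff"` or `"ascii"`.
#' @export
write_height_map <- function(map, path, format = c("tiff", "ascii")) {
  stopifnot(inherits(map, "height_map"))
  format <- match.arg(format)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  if (format == "tiff") {
    write_float_tiff(map$heights, path)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    apply(map$heights, 1L, function(r)
      writeLines(paste(formatC(r, digits = 9, format = "g"), collapse = " "), con))
  }
  invisible(path)
}

is_tiff_file <- function(path) {
  magic <- readBin(path, "raw", n = 4L)
  identical(magic, as.raw(c(0x49, 0x49, 0x2a, 0x00))) ||
    identical(magic, as.raw(c(0x4d, 0x4d, 0x00, 0x2a)))
}

# Minimal little-endian, single-strip, 32-bit IEEE-float grayscale TIFF
# writer. Heights in nm routinely exceed [0,1] and may be negative, which
# rules out integer-normalised storage; samples are written verbatim so
# the round trip is bit-exact at single precision.
write_float_tiff <- function(m, path) {
  h <- nrow(m); w <- ncol(m)
  n_tags <- 10L
  ifd_offset <- 8L
  data_offset <- ifd_offset + 2L + n_tags * 12L + 4L
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)           # II, magic 42
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  writeBin(n_tags, con, size = 2, endian = "little")
  tag <- function(id, type, count, value) {
    writeBin(as.integer(id), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  tag(256, 4, 1, w)                    # ImageWidth
  tag(257, 4, 1, h)                    # ImageLength
  tag(258, 3, 1, 32)                   # BitsPerSample
  tag(259, 3, 1, 1)                    # Compression: none
  tag(262, 3, 1, 1)                    # Photometric: BlackIsZero
  tag(273, 4, 1, data_offset)          # StripOffsets
  tag(277, 3, 1, 1)                    # SamplesPerPixel
  tag(278, 4, 1, h)                    # RowsPerStrip
  tag(279, 4, 1, w * h * 4L)           # StripByteCounts
  tag(339, 3, 1, 3)                    # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # no next IFD
  # row-major pixel order: transpose since R matrices are column-major
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  invisible(path)
}
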