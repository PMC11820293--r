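#' Construct a thermal frame
#'
#' A thermal frame is one single-band temperature raster (degrees Celsius)
#' acquired on one measurement date, together with its acquisition
#' metadata.  Pixel values may contain `NaN` for dropped sensor readings;
#' `NaN` pixels are excluded from all downstream means.
#'
#' @param pixels Numeric matrix of temperatures in degrees Celsius.
#'   Non-`NaN` values must be finite.
#' @param date Day index of acquisition within the season (numeric).
#' @param season Season label (character scalar), e.g. `"S1"`.
#' @param meta Named list of acquisition metadata; recognised entries are
#'   `ambient_c` (air temperature, degrees C) and `rh_pct` (relative
#'   humidity, percent).  Temperatures are assumed already calibrated for
#'   atmosphere and emissivity upstream.
#' @return An object of class `thermal_frame`.
#' @export
thermal_frame <- function(pixels, date, season, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (length(pixels) == 0L) stop("`pixels` must be non-empty", call. = FALSE)
  bad <- !is.finite(pixels) & !is.nan(pixels)
  if (any(bad)) {
    stop("`pixels` contains non-finite values other than NaN (Inf/NA)",
         call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      date = as.numeric(date),
      season = as.character(season),
      meta = meta
    ),
    class = "thermal_frame"
  )
}

#' @export
print.thermal_frame <- function(x, ...) {
  cat(sprintf(
    "<thermal_frame> %dx%d px, season %s, day %g, %d NaN px\n",
    nrow(x$pixels), ncol(x$pixels), x$season, x$date, sum(is.nan(x$pixels))
  ))
  invisible(x)
}

# Tag ids for the minimal TIFF IFD written below.
.tiff_tags <- function(w, h) {
  # tag, type (3 = SHORT, 4 = LONG), value
  list(
    c(256L, 4L, w),           # ImageWidth
    c(257L, 4L, h),           # ImageLength
    c(258L, 3L, 32L),         # BitsPerSample
    c(259L, 3L, 1L),          # Compression = none
    c(262L, 3L, 1L),          # Photometric = BlackIsZero
    c(273L, 4L, 8L),          # StripOffsets: data follows the header
    c(277L, 3L, 1L),          # SamplesPerPixel
    c(278L, 4L, h),           # RowsPerStrip: single strip
    c(279L, 4L, 4L * w * h),  # StripByteCounts
    c(339L, 3L, 3L)           # SampleFormat = IEEE float
  )
}

#' Write a thermal frame as a 32-bit float TIFF
#'
#' Writes a single-band, single-strip, uncompressed little-endian TIFF
#' with IEEE-float samples (SampleFormat 3), the storage the pipeline's
#' rasters use.  Values are stored at 32-bit float precision, so a frame
#' whose pixels are representable in 32 bits round-trips bitwise through
#' [read_frame()]; `NaN` pixels are preserved.
#'
#' @param frame A [thermal_frame()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "thermal_frame"))
  m <- frame$pixels
  h <- nrow(m); w <- ncol(m)
  con <- file(path, "wb")
  on.exit(close(con))
  # header: little-endian magic, IFD placed after the pixel strip
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L + 4L * w * h, con, size = 4, endian = "little")
  # pixel strip, row-major scanlines, 4-byte IEEE floats
  writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  # IFD
  tags <- .tiff_tags(w, h)
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(1L, con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT packed into the first two value bytes
      writeBin(tg[3], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[3], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

#' Read a thermal frame from a 32-bit float TIFF
#'
#' Accepts only single-band rasters with IEEE-float samples; multi-band or
#' integer-quantised files are a format error.  `NaN` pixels load as `NaN`
#' and are excluded from plot means by [extract_ct()].
#'
#' @param path Path to a single-band float TIFF (degrees Celsius).
#' @param date,season,meta Acquisition metadata attached to the frame (the
#'   raster format itself carries none); see [thermal_frame()].
#' @return A [thermal_frame()].
#' @export
read_frame <- function(path, date = NA_real_, season = NA_character_,
                       meta = list()) {
  px <- tiff::readTIFF(path, info = TRUE)
  info <- attributes(px)
  if (!is.matrix(px) || isTRUE(info$samples.per.pixel > 1L)) {
    stop("not a single-band raster: ", path, call. = FALSE)
  }
  if (!identical(info$sample.format, "float")) {
    stop("not a float raster (sample format ",
         info$sample.format %||% "unknown", "): ", path, call. = FALSE)
  }
  attributes(px) <- list(dim = dim(px))
  thermal_frame(px, date = date, season = season, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
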