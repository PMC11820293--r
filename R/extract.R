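#' Threshold-based soil mask
#'
#' Bare soil radiates hotter than a transpiring canopy in midday thermal
#' imagery, so pixels above a temperature threshold are masked out before
#' plot means are taken.  This replaces the manual "draw the ROI around
#' the soil" step of interactive thermal software with an explicit,
#' testable rule.
#'
#' @param frame A [thermal_frame()].
#' @param threshold Temperature in degrees Celsius; a pixel is masked iff
#'   its value is strictly greater than `threshold`.  `Inf` masks nothing.
#' @return Logical matrix, `TRUE` = masked.  `NaN` pixels are never
#'   masked here; they are excluded separately by [extract_ct()].
#' @export
apply_soil_mask <- function(frame, threshold) {
  stopifnot(inherits(frame, "thermal_frame"))
  if (is.na(threshold)) stop("`threshold` must not be NA", call. = FALSE)
  m <- frame$pixels > threshold
  m[is.nan(frame$pixels)] <- FALSE
  m
}

#' Extract per-plot mean canopy temperature
#'
#' For each plot region in the layout, the plain arithmetic mean of the
#' unmasked, non-`NaN` pixels inside the plot's half-open bounds.  Pixels
#' outside plot bounds never influence any mean.
#'
#' @param frame A [thermal_frame()].
#' @param layout A [plot_layout()] whose bounds fit the frame.
#' @param mask Optional logical matrix of the frame's dimensions (`TRUE` =
#'   masked), typically from [apply_soil_mask()]; or a single numeric soil
#'   threshold in degrees C, applied via [apply_soil_mask()].
#' @return Data frame with one row per plot: `line`, `season`, `date`,
#'   `replicate`, `plot_id`, `ct_mean` (degrees C), `n_pixels` (pixels
#'   contributing to the mean), `n_masked` (pixels excluded by the mask or
#'   `NaN`).
#' @export
extract_ct <- function(frame, layout, mask = NULL) {
  stopifnot(inherits(frame, "thermal_frame"), inherits(layout, "plot_layout"))
  px <- frame$pixels
  if (!identical(dim(px), as.integer(layout$raster_dim))) {
    stop("frame dimensions ", nrow(px), "x", ncol(px),
         " do not match layout raster ", layout$raster_dim[1], "x",
         layout$raster_dim[2], call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- matrix(FALSE, nrow(px), ncol(px))
  } else if (is.numeric(mask) && length(mask) == 1L) {
    mask <- apply_soil_mask(frame, mask)
  }
  stopifnot(is.logical(mask), identical(dim(mask), dim(px)))
  p <- layout$plots
  out <- p[, c("line_id", "replicate", "plot_id")]
  names(out)[1] <- "line"
  out$season <- frame$season
  out$date <- frame$date
  out$ct_mean <- NA_real_
  out$n_pixels <- NA_integer_
  out$n_masked <- NA_integer_
  for (i in seq_len(nrow(p))) {
    rows <- (p$row0[i] + 1L):p$row1[i]   # half-open 0-based -> 1-based
    cols <- (p$col0[i] + 1L):p$col1[i]
    vals <- px[rows, cols]
    drop <- mask[rows, cols] | is.nan(vals)
    keep <- vals[!drop]
    if (length(keep) == 0L) {
      stop("plot ", p$plot_id[i], " is fully masked on season ",
           frame$season, " day ", frame$date, call. = FALSE)
    }
    out$ct_mean[i] <- mean(keep)
    out$n_pixels[i] <- length(keep)
    out$n_masked[i] <- sum(drop)
  }
  rownames(out) <- NULL
  out[, c("line", "season", "date", "replicate", "plot_id",
          "ct_mean", "n_pixels", "n_masked")]
}

#' Extract CT from a list of frames
#'
#' Convenience wrapper applying [extract_ct()] across frames and binding
#' rows into one CT table.
#'
#' @inheritParams extract_ct
#' @param frames List of [thermal_frame()] objects.
#' @param mask_threshold Optional soil threshold in degrees C applied to
#'   every frame.
#' @return Row-bound CT table (see [extract_ct()]).
#' @export
extract_ct_frames <- function(frames, layout, mask_threshold = NULL) {
  do.call(rbind, lapply(frames, extract_ct, layout = layout,
                        mask = mask_threshold))
}
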