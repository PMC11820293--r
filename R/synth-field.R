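#' Specify a synthetic thermal field trial
#'
#' Describes a regular planting grid of rectangular plots imaged by a
#' thermal camera: each line (genotype) occupies `plots_per_line`
#' replicate plots placed at random grid positions (a randomised design),
#' separated by bare-soil gaps that image hotter than the canopy.  The
#' per-plot canopy temperature before sensor noise is
#' `ambient[season] + offset[line] + slope[line, season] * day`.
#'
#' @param n_lines Number of lines (genotypes).
#' @param plots_per_line Replicate plots per line.
#' @param grid Integer `c(rows, cols)` of the planting grid; must hold at
#'   least `n_lines * plots_per_line` plots.
#' @param plot_px Side length of each plot region, pixels.
#' @param gap_px Width of the soil gap between plots, pixels.
#' @param ambient Named numeric vector of base ambient temperature per
#'   season, degrees C.  The default carries a +1.5 degree global offset
#'   in the second season, emulating a warmer measurement year that
#'   neighbour normalization must cancel.
#' @param offsets Per-line CT offset, degrees C (ground truth).  Either a
#'   numeric vector of length `n_lines` or `NULL` to draw from
#'   `N(0, offset_sd)`.
#' @param offset_sd Standard deviation used when drawing `offsets`.
#' @param slopes Per-line, per-season linear CT trend, degrees C per day:
#'   an `n_lines x n_seasons` matrix, a length-`n_lines` vector recycled
#'   across seasons, or a scalar.
#' @param soil_margin Soil is hotter than ambient by this margin,
#'   degrees C.  Positive by default so that threshold masking is
#'   exercised.
#' @param noise_sd Per-pixel sensor noise standard deviation, degrees C.
#' @param seed Integer seed; a fixed seed makes every generated artefact
#'   bit-identical across runs.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(n_lines, plots_per_line = 3L, grid = c(6L, 10L),
                       plot_px = 12L, gap_px = 3L,
                       ambient = c(S1 = 25, S2 = 26.5),
                       offsets = NULL, offset_sd = 0.8,
                       slopes = 0, soil_margin = 8, noise_sd = 0.2,
                       seed = 1L) {
  n_lines <- as.integer(n_lines)
  plots_per_line <- as.integer(plots_per_line)
  grid <- as.integer(grid)
  if (n_lines * plots_per_line > prod(grid)) {
    stop("grid ", grid[1], "x", grid[2], " too small for ",
         n_lines * plots_per_line, " plots", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(names(ambient))) {
    names(ambient) <- paste0("S", seq_along(ambient))
  }
  n_seasons <- length(ambient)
  if (is.null(offsets)) {
    offsets <- withr::with_seed(seed + 1L, stats::rnorm(n_lines, 0, offset_sd))
  }
  stopifnot(length(offsets) == n_lines)
  slopes <- if (is.matrix(slopes)) slopes else
    matrix(slopes, n_lines, n_seasons)
  stopifnot(nrow(slopes) == n_lines, ncol(slopes) == n_seasons)
  lid <- sprintf("L%02d", seq_len(n_lines))
  structure(
    list(
      n_lines = n_lines, plots_per_line = plots_per_line, grid = grid,
      plot_px = as.integer(plot_px), gap_px = as.integer(gap_px),
      ambient = ambient,
      offsets = stats::setNames(offsets, lid),
      slopes = matrix(slopes, n_lines, n_seasons,
                      dimnames = list(lid, names(ambient))),
      soil_margin = soil_margin, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "field_spec"
  )
}

#' Specify a field with planted cold/warm/mediate line types
#'
#' Convenience constructor planting ground-truth temperature types for
#' classification-recovery studies: cold lines carry a negative relative
#' CT offset and a falling within-season trend in both seasons, warm
#' lines the mirror image, and mediate lines sit at zero offset with a
#' trend whose sign flips between seasons (the unstable behaviour that
#' defines the type).
#'
#' @param n_cold,n_warm,n_mediate Lines per planted type.
#' @param class_offset Magnitude of the cold/warm CT offset, degrees C.
#' @param class_slope Magnitude of the within-season trend, degrees C/day.
#' @param ... Passed to [field_spec()] (grid, noise, seed, ...).
#' @return A `field_spec` with an extra `truth_type` element (named
#'   character vector of planted labels).
#' @export
typed_field_spec <- function(n_cold, n_warm, n_mediate,
                             class_offset = 0.8, class_slope = 0.1, ...) {
  n <- n_cold + n_warm + n_mediate
  type <- rep(c("cold", "warm", "mediate"), c(n_cold, n_warm, n_mediate))
  offsets <- c(rep(-class_offset, n_cold), rep(class_offset, n_warm),
               rep(0, n_mediate))
  s1 <- c(rep(-class_slope, n_cold), rep(class_slope, n_warm),
          rep(class_slope, n_mediate))
  s2 <- c(rep(-class_slope, n_cold), rep(class_slope, n_warm),
          rep(-class_slope, n_mediate))
  spec <- field_spec(n_lines = n, offsets = offsets,
                     slopes = cbind(s1, s2), ...)
  spec$slopes <- matrix(cbind(s1, s2), n, 2,
                        dimnames = list(names(spec$offsets),
                                        names(spec$ambient)[1:2]))
  spec$truth_type <- stats::setNames(type, names(spec$offsets))
  spec
}

# Deterministic random assignment of lines to grid cells and the derived
# plot geometry + six-neighbour adjacency.
.field_layout <- function(spec) {
  rows <- spec$grid[1]; cols <- spec$grid[2]
  n_plots <- spec$n_lines * spec$plots_per_line
  cells <- withr::with_seed(spec$seed, sample.int(rows * cols, n_plots))
  gr <- (cells - 1L) %/% cols + 1L
  gc <- (cells - 1L) %% cols + 1L
  line <- rep(names(spec$offsets), each = spec$plots_per_line)
  repl <- rep(seq_len(spec$plots_per_line), spec$n_lines)
  pid <- sprintf("P%03d", seq_len(n_plots))
  stride <- spec$plot_px + spec$gap_px
  plots <- data.frame(
    plot_id = pid, line_id = line, replicate = repl,
    row0 = spec$gap_px + (gr - 1L) * stride,
    col0 = spec$gap_px + (gc - 1L) * stride,
    grid_row = gr, grid_col = gc,
    stringsAsFactors = FALSE
  )
  plots$row1 <- plots$row0 + spec$plot_px
  plots$col1 <- plots$col0 + spec$plot_px
  dim_r <- rows * stride + spec$gap_px
  dim_c <- cols * stride + spec$gap_px
  # six nearest plots on the planting grid: E, W, N, S, NE, SW -- a
  # symmetric hex-like neighbourhood, truncated at field edges and at
  # unplanted cells
  key <- paste(plots$grid_row, plots$grid_col)
  adjacency <- lapply(seq_len(n_plots), function(i) {
    r <- plots$grid_row[i]; c <- plots$grid_col[i]
    nb <- rbind(c(r, c + 1), c(r, c - 1), c(r - 1, c), c(r + 1, c),
                c(r - 1, c + 1), c(r + 1, c - 1))
    hit <- match(paste(nb[, 1], nb[, 2]), key)
    plots$plot_id[hit[!is.na(hit)]]
  })
  names(adjacency) <- pid
  plot_layout(plots, adjacency, c(dim_r, dim_c))
}

#' Generate synthetic thermal frames with ground truth
#'
#' Renders one thermal raster per measurement date: plot regions at their
#' true canopy temperature, soil everywhere else at
#' `ambient + soil_margin`, and i.i.d. Gaussian sensor noise on every
#' pixel.  The same `field_spec` yields the same plot layout in every
#' season (one physical field), while the noise stream differs per
#' season, so two seasons are two acquisitions of one trial.
#'
#' @param spec A [field_spec()].
#' @param dates Numeric day indices of the measurement dates within the
#'   season.
#' @param season Season label; must name an entry of `spec$ambient`.
#' @return A list with `frames` (list of [thermal_frame()], one per
#'   date), `layout` (the [plot_layout()]), `truth` (data frame `line`,
#'   `season`, `date`, `replicate`, `plot_id`, `ct_true` in degrees C:
#'   the noiseless plot temperature), and `soil_mask` (logical matrix,
#'   `TRUE` over soil pixels).
#' @export
make_thermal_frames <- function(spec, dates = c(0, 4, 7, 10, 17),
                                season = names(spec$ambient)[1]) {
  stopifnot(inherits(spec, "field_spec"))
  if (!season %in% names(spec$ambient)) {
    stop("unknown season ", season, "; spec has: ",
         paste(names(spec$ambient), collapse = ", "), call. = FALSE)
  }
  layout <- .field_layout(spec)
  amb <- spec$ambient[[season]]
  p <- layout$plots
  soil <- matrix(TRUE, layout$raster_dim[1], layout$raster_dim[2])
  for (i in seq_len(nrow(p))) {
    soil[(p$row0[i] + 1L):p$row1[i], (p$col0[i] + 1L):p$col1[i]] <- FALSE
  }
  si <- match(season, names(spec$ambient))
  truth <- do.call(rbind, lapply(dates, function(d) {
    data.frame(
      line = p$line_id, season = season, date = d, replicate = p$replicate,
      plot_id = p$plot_id,
      ct_true = amb + spec$offsets[p$line_id] +
        spec$slopes[p$line_id, si] * d,
      stringsAsFactors = FALSE
    )
  }))
  rownames(truth) <- NULL
  frames <- withr::with_seed(spec$seed + 7919L * si, {
    lapply(seq_along(dates), function(k) {
      d <- dates[k]
      px <- matrix(amb + spec$soil_margin,
                   layout$raster_dim[1], layout$raster_dim[2])
      for (i in seq_len(nrow(p))) {
        px[(p$row0[i] + 1L):p$row1[i], (p$col0[i] + 1L):p$col1[i]] <-
          amb + spec$offsets[p$line_id[i]] + spec$slopes[p$line_id[i], si] * d
      }
      if (spec$noise_sd > 0) {
        px <- px + matrix(stats::rnorm(length(px), 0, spec$noise_sd),
                          nrow(px), ncol(px))
      }
      thermal_frame(px, date = d, season = season,
                    meta = list(ambient_c = amb, rh_pct = 60))
    })
  })
  list(frames = frames, layout = layout, truth = truth, soil_mask = soil)
}
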