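#' Neighbour-normalized (relative) canopy temperature
#'
#' Raw plot CT confounds genotype with ambient conditions at acquisition
#' time.  Subtracting the mean CT of each plot's neighbours on the same
#' date removes effects shared locally across the field — in particular a
#' global between-season temperature offset — leaving a relative CT on
#' which lines can be compared across dates and seasons.  For each plot
#' `p`: `rel(p) = CT(p) - mean{CT(q) : q adjacent to p}`; replicate plots
#' of a line are then averaged to one value per (line, season, date).
#'
#' @param ct CT table from [extract_ct_frames()] (columns `line`,
#'   `season`, `date`, `replicate`, `plot_id`, `ct_mean`).
#' @param layout A [plot_layout()] supplying the adjacency; alternatively
#'   a named list mapping plot id to neighbour ids.
#' @param order `"plot"` (default) normalizes each replicate plot against
#'   its own neighbours before averaging replicates to line level;
#'   `"line"` first replaces every plot's CT by its line mean and then
#'   applies the same spatial subtraction.  The plot-level order is the
#'   default because normalization corrects a spatial effect, which acts
#'   on plots, while results are reported per line.
#' @return Data frame `line`, `season`, `date`, `rel_ct` (degrees C), one
#'   row per (line, season, date).
#' @export
normalize_ct <- function(ct, layout, order = c("plot", "line")) {
  order <- match.arg(order)
  adjacency <- if (inherits(layout, "plot_layout")) layout$adjacency else layout
  ct <- as.data.frame(ct)
  isolated <- names(adjacency)[lengths(adjacency) == 0L]
  isolated <- intersect(isolated, ct$plot_id)
  if (length(isolated)) {
    stop("plot(s) with no neighbours cannot be normalized: ",
         paste(isolated, collapse = ", "), call. = FALSE)
  }
  val <- ct$ct_mean
  if (order == "line") {
    lm_key <- interaction(ct$line, ct$season, ct$date, drop = TRUE)
    val <- stats::ave(ct$ct_mean, lm_key)
  }
  ct$.val <- val
  rel <- do.call(rbind, lapply(
    split(ct, interaction(ct$season, ct$date, drop = TRUE)),
    function(g) {
      idx <- stats::setNames(seq_len(nrow(g)), g$plot_id)
      g$rel_ct <- vapply(seq_len(nrow(g)), function(i) {
        nb <- adjacency[[g$plot_id[i]]]
        have <- nb %in% g$plot_id
        if (!all(have)) {
          warning("plot ", g$plot_id[i], " (", g$season[1], " day ",
                  g$date[1], "): neighbour(s) without CT dropped: ",
                  paste(nb[!have], collapse = ", "), call. = FALSE)
        }
        nb <- nb[have]
        if (length(nb) == 0L) {
          stop("plot ", g$plot_id[i], " has no neighbour with CT on ",
               g$season[1], " day ", g$date[1], call. = FALSE)
        }
        g$.val[i] - mean(g$.val[idx[nb]])
      }, numeric(1))
      g
    }
  ))
  agg <- stats::aggregate(rel_ct ~ line + season + date, data = rel, FUN = mean)
  agg <- agg[order(agg$line, agg$season, agg$date), ]
  rownames(agg) <- NULL
  agg
}

#' Between-season raw CT offset per paired date
#'
#' Measurement campaigns in different seasons share date labels (first
#' date, second date, ...); this reports, per shared date, the
#' field-mean raw CT difference `mean(season 2) - mean(season 1)` — the
#' global environmental offset that relative CT is designed to cancel.
#'
#' @param ct CT table (columns `season`, `date`, `ct_mean`) covering
#'   exactly two seasons.
#' @param seasons Optional character vector of the two season labels in
#'   order; defaults to sorted unique labels.
#' @return Data frame `date`, `mean_s1`, `mean_s2`, `diff` (degrees C).
#'   Dates present in only one season are excluded with a warning.
#' @export
season_offset_check <- function(ct, seasons = NULL) {
  ct <- as.data.frame(ct)
  if (is.null(seasons)) seasons <- sort(unique(ct$season))
  if (length(seasons) != 2L) {
    stop("need exactly two seasons, got: ",
         paste(seasons, collapse = ", "), call. = FALSE)
  }
  m <- stats::aggregate(ct_mean ~ season + date, data = ct, FUN = mean)
  d1 <- m[m$season == seasons[1], ]
  d2 <- m[m$season == seasons[2], ]
  shared <- intersect(d1$date, d2$date)
  lone <- setdiff(union(d1$date, d2$date), shared)
  if (length(lone)) {
    warning("date(s) present in only one season excluded: ",
            paste(lone, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    date = shared,
    mean_s1 = d1$ct_mean[match(shared, d1$date)],
    mean_s2 = d2$ct_mean[match(shared, d2$date)]
  )
  out$diff <- out$mean_s2 - out$mean_s1
  out[order(out$date), ]
}
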