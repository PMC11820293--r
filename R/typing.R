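#' Within-season CT trend slope
#'
#' Ordinary least-squares slope of relative CT on the day index within
#' one season — the "maintains a decreasing/increasing trend" statistic
#' that drives temperature-type classification.
#'
#' @param date Day indices (numeric, at least 3 distinct values).
#' @param rel_ct Relative CT at those days, degrees C.
#' @return Slope in degrees C per day.
#' @export
trend_slope <- function(date, rel_ct) {
  if (length(date) < 3L) {
    stop("need at least 3 dates to estimate a trend", call. = FALSE)
  }
  stopifnot(length(date) == length(rel_ct))
  unname(stats::coef(stats::lm(rel_ct ~ date))[2])
}

#' Classify lines into cold-, warm- and mediate-temperature types
#'
#' A line is cold-type when its relative CT both trends downward
#' (slope `< -epsilon`) and averages below zero in *every* season;
#' warm-type when it trends upward (slope `> +epsilon`) with a positive
#' mean in every season; everything else — including lines whose trend
#' flips sign between seasons — is mediate-type.  Requiring both the
#' trend and the mean-sign condition, in all seasons, is the conservative
#' reading of selection "based on the trends and averages" of relative
#' CT; the tolerance `epsilon` keeps near-zero slopes from forcing a
#' cold/warm call.
#'
#' @param rel Relative CT table from [normalize_ct()] (columns `line`,
#'   `season`, `date`, `rel_ct`), covering at least two seasons per line.
#' @param epsilon Slope tolerance, degrees C per day (default 0.01).
#' @return Data frame with one row per line: `line`, `call` (one of
#'   `"cold"`, `"warm"`, `"mediate"`), and per-season columns
#'   `slope_<season>` (degrees C/day) and `mean_<season>` (degrees C).
#' @export
classify_lines <- function(rel, epsilon = 0.01) {
  rel <- as.data.frame(rel)
  seasons <- sort(unique(rel$season))
  out <- do.call(rbind, lapply(split(rel, rel$line), function(g) {
    have <- sort(unique(g$season))
    if (length(have) < 2L) {
      stop("line ", g$line[1], " observed in fewer than 2 seasons",
           call. = FALSE)
    }
    if (!setequal(have, seasons)) {
      stop("line ", g$line[1], " missing season(s): ",
           paste(setdiff(seasons, have), collapse = ", "), call. = FALSE)
    }
    slopes <- vapply(seasons, function(s) {
      gs <- g[g$season == s, ]
      trend_slope(gs$date, gs$rel_ct)
    }, numeric(1))
    means <- vapply(seasons, function(s) mean(g$rel_ct[g$season == s]),
                    numeric(1))
    call <- if (all(slopes < -epsilon) && all(means < 0)) {
      "cold"
    } else if (all(slopes > epsilon) && all(means > 0)) {
      "warm"
    } else {
      "mediate"
    }
    row <- data.frame(line = g$line[1], call = call,
                      stringsAsFactors = FALSE)
    row[paste0("slope_", seasons)] <- as.list(slopes)
    row[paste0("mean_", seasons)] <- as.list(means)
    row
  }))
  rownames(out) <- NULL
  out[order(out$line), ]
}
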