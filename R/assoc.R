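#' Pearson correlation panel with significance stars
#'
#' All pairwise Pearson correlations among the requested variables, with
#' two-sided p-values from the t-distribution on `n - 2` degrees of
#' freedom and the usual star convention: `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05.  Missing values are deleted pairwise.  A pair involving
#' a zero-variance variable, or with fewer than 3 complete observations,
#' is reported as undefined (`NA`), never as zero.
#'
#' @param table Data frame of per-observation trait values (one row per
#'   line x date, missing values allowed).
#' @param variables Character vector of column names to correlate.
#' @param by Optional grouping column name (e.g. `date`): the panel is
#'   computed separately within each group.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; the default `"none"` reports per-cell stars,
#'   `"BH"` applies Benjamini-Hochberg across the panel's unique pairs.
#' @return Data frame `var1`, `var2`, `r`, `p`, `star`, `n` (plus the
#'   grouping column when `by` is given), containing every ordered pair
#'   including the unit diagonal.
#' @export
correlation_panel <- function(table, variables, by = NULL,
                              p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  table <- as.data.frame(table)
  miss <- setdiff(variables, names(table))
  if (length(miss)) {
    stop("variables absent from table: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  groups <- if (is.null(by)) list(table) else split(table, table[[by]])
  out <- do.call(rbind, lapply(names(groups) %||% "", function(gn) {
    g <- if (is.null(by)) table else groups[[gn]]
    pairs <- expand.grid(var1 = variables, var2 = variables,
                         stringsAsFactors = FALSE)
    cells <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      .corr_cell(g[[pairs$var1[i]]], g[[pairs$var2[i]]])
    }))
    res <- cbind(pairs, cells)
    if (p_adjust == "BH") {
      off <- res$var1 < res$var2 & !is.na(res$p)
      adj <- stats::p.adjust(res$p[off], method = "BH")
      res$p[off] <- adj
      # mirror onto the symmetric cells
      key <- paste(pmin(res$var1, res$var2), pmax(res$var1, res$var2))
      res$p <- res$p[match(key, key)]
    }
    res$star <- star_for_p(res$p)
    if (!is.null(by)) res[[by]] <- g[[by]][1]
    res
  }))
  rownames(out) <- NULL
  out
}

.corr_cell <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x[ok], y[ok])
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  data.frame(r = r, p = p, n = n)
}

#' Significance stars for p-values
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"***"` below 0.001, `"**"` below 0.01,
#'   `"*"` below 0.05, otherwise `""`; `NA` p gives `NA`.
#' @export
star_for_p <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Contrast a trait between temperature-type groups
#'
#' Group means, the cold-minus-warm absolute and percent difference
#' (percent of the warm mean), a Welch two-sample test, and a compact
#' letter display across all groups for bar-chart annotation.  Welch's
#' unequal-variance test is used throughout because type groups are often
#' tiny (two lines per type is common), making pooled-variance
#' assumptions indefensible; with a group of size 1 the difference is
#' still reported but the test is skipped with a warning.
#'
#' @param table Data frame with a `line` column and the trait column.
#' @param calls Type calls from [classify_lines()] (columns `line`,
#'   `call`), or any data frame mapping `line` to a group label in
#'   `call`.
#' @param trait Name of the trait column in `table`.
#' @param groups The two groups contrasted (difference = first minus
#'   second, percent of the second's mean).
#' @param alpha Significance level for the letter display.
#' @return List with `means` (data frame `group`, `n`, `mean`, `sd`,
#'   `letter`), `diff` (first minus second group mean), `pct_diff`
#'   (percent), `p` (Welch p, `NA` when skipped).
#' @export
group_contrast <- function(table, calls, trait,
                           groups = c("cold", "warm"), alpha = 0.05) {
  table <- as.data.frame(table)
  calls <- as.data.frame(calls)
  g <- calls$call[match(table$line, calls$line)]
  keep <- !is.na(g) & !is.na(table[[trait]])
  x <- table[[trait]][keep]
  g <- g[keep]
  lv <- unique(g)
  if (!all(groups %in% lv)) {
    stop("group(s) absent: ", paste(setdiff(groups, lv), collapse = ", "),
         call. = FALSE)
  }
  means <- data.frame(
    group = lv,
    n = as.integer(table(g)[lv]),
    mean = vapply(lv, function(l) mean(x[g == l]), numeric(1)),
    sd = vapply(lv, function(l) stats::sd(x[g == l]), numeric(1)),
    stringsAsFactors = FALSE
  )
  x1 <- x[g == groups[1]]; x2 <- x[g == groups[2]]
  dd <- mean(x1) - mean(x2)
  pct <- 100 * dd / mean(x2)
  if (length(x1) < 2L || length(x2) < 2L) {
    warning("a contrast group has size 1; Welch test skipped",
            call. = FALSE)
    p <- NA_real_
  } else {
    # zero variance in both groups leaves the Welch statistic undefined
    p <- tryCatch(stats::t.test(x1, x2)$p.value,
                  error = function(e) NA_real_)
  }
  means$letter <- .compact_letters(x, g, lv, alpha)
  rownames(means) <- NULL
  list(means = means, diff = dd, pct_diff = pct, p = p)
}

# Insert-and-absorb compact letter display from pairwise Welch tests.
# Groups of size 1 are never declared different (their tests are
# undefined), so they share letters with everything.
.compact_letters <- function(x, g, lv, alpha) {
  k <- length(lv)
  differ <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      xi <- x[g == lv[i]]; xj <- x[g == lv[j]]
      if (length(xi) >= 2 && length(xj) >= 2 &&
          (stats::sd(xi) > 0 || stats::sd(xj) > 0)) {
        differ[i, j] <- differ[j, i] <-
          stats::t.test(xi, xj)$p.value < alpha
      }
    }
  }
  # letter sets: start with one set holding everyone, split on conflicts
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!differ[i, j]) next
      for (s in seq_along(sets)) {
        if (all(c(i, j) %in% sets[[s]])) {
          a <- setdiff(sets[[s]], i); b <- setdiff(sets[[s]], j)
          sets[[s]] <- a
          if (!any(vapply(sets, function(t) all(b %in% t), logical(1)))) {
            sets[[length(sets) + 1L]] <- b
          }
        }
      }
    }
  }
  sets <- sets[lengths(sets) > 0]
  vapply(seq_len(k), function(i) {
    paste0(letters[which(vapply(sets, function(s) i %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' Per-line dry-matter change between two sampling dates
#'
#' The difference in dry weight between a later and an earlier sampling
#' date (later minus earlier), per line and organ — positive values mean
#' accumulation over the interval.
#'
#' @param weights Data frame `line`, `organ`, `dap` (days after
#'   anthesis), `weight_g`.
#' @param dap_from,dap_to The two sampling dates; delta =
#'   `weight(dap_to) - weight(dap_from)`.
#' @param organs Organs to report (default: all present).
#' @return Data frame `line`, `organ`, `delta_g`.  Lines missing either
#'   date are skipped with a warning.
#' @export
dry_matter_delta <- function(weights, dap_from = 27, dap_to = 33,
                             organs = NULL) {
  weights <- as.data.frame(weights)
  if (is.null(organs)) organs <- unique(weights$organ)
  out <- list(); skipped <- character()
  for (org in organs) {
    w <- weights[weights$organ == org, ]
    for (ln in unique(w$line)) {
      w1 <- w$weight_g[w$line == ln & w$dap == dap_from]
      w2 <- w$weight_g[w$line == ln & w$dap == dap_to]
      if (length(w1) != 1L || length(w2) != 1L) {
        skipped <- c(skipped, paste0(ln, "/", org))
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        line = ln, organ = org, delta_g = w2 - w1, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("line/organ missing a sampling date, skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (!length(out)) return(data.frame(line = character(),
                                      organ = character(),
                                      delta_g = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rainfall window summary
#'
#' Total rainfall inside a window of days, the season (period) total, and
#' the window's share of the period as a percent — reported both at full
#' precision and rounded to the integer percent conventionally quoted.
#'
#' @param weather Weather data frame from [make_weather()] /
#'   [read_weather()].
#' @param window Two-element numeric `c(first_day, last_day)`, inclusive,
#'   within the period covered by `weather`.
#' @return List `window_mm`, `period_mm`, `fraction_pct` (full
#'   precision), `fraction_pct_rounded` (integer percent).
#' @export
weather_summary <- function(weather, window) {
  weather <- as.data.frame(weather)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (window[1] < min(weather$day) || window[2] > max(weather$day)) {
    stop("window outside the weather period", call. = FALSE)
  }
  in_win <- weather$day >= window[1] & weather$day <= window[2]
  window_mm <- sum(weather$rain_mm[in_win])
  period_mm <- sum(weather$rain_mm)
  if (period_mm == 0) {
    frac <- NA_real_
  } else {
    frac <- 100 * window_mm / period_mm
  }
  list(window_mm = window_mm, period_mm = period_mm,
       fraction_pct = frac,
       fraction_pct_rounded = if (is.na(frac)) NA_real_ else round(frac))
}
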