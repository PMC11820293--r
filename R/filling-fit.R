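#' Fit the logistic grain-filling model to one series
#'
#' Nonlinear least squares for `y(t) = k / (1 + a exp(-b t))` on a
#' thousand-grain-weight series, by Levenberg-Marquardt
#' ([minpack.lm::nlsLM]).  Starting values come from log-linearisation:
#' with a provisional ceiling `k0` slightly above the largest observed
#' weight, `ln(k0/y - 1)` is linear in `t` with slope `-b` and intercept
#' `ln(a)`, which is robust for sigmoid data without user tuning.  If
#' that start fails to converge, a coarse multi-start grid over
#' plausible `(k, a, b)` is tried.  The goodness-of-fit screen follows
#' the convention for grain-filling curves: a fit is flagged adequate
#' only when R-squared exceeds 0.95, and clearly non-sigmoid data fail
#' the screen rather than being silently accepted.
#'
#' @param t Sampling days (day 0 = 27 days after anthesis), strictly
#'   increasing, length >= 4 (three free parameters).
#' @param y Thousand-grain dry weight, grams, all `>= 0`, not all equal.
#' @param r2_adequate Adequacy threshold on R-squared (default 0.95).
#' @return An object of class `logistic_fit`: list with `k`, `a`, `b`,
#'   `r2`, `adequate` (logical), `n`, `fitted`, `residuals`.
#' @export
fit_logistic <- function(t, y, r2_adequate = 0.95) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop("t and y differ in length", call. = FALSE)
  if (length(t) < 4L) {
    stop("need >= 4 observations to fit 3 parameters", call. = FALSE)
  }
  if (is.unsorted(t, strictly = TRUE)) {
    stop("`t` must be strictly increasing", call. = FALSE)
  }
  if (any(y < 0)) stop("weights must be >= 0", call. = FALSE)
  if (stats::sd(y) == 0) stop("`y` is constant; nothing to fit", call. = FALSE)

  starts <- .logistic_starts(t, y)
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ k / (1 + a * exp(-b * t)),
        start = st,
        lower = c(k = max(y) * 0.5, a = 1e-8, b = 1e-8),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    stop("logistic fit failed to converge from all initializations ",
         "(n = ", length(t), ", y range ", signif(min(y), 4), "-",
         signif(max(y), 4), " g)", call. = FALSE)
  }
  cf <- stats::coef(fit)
  yhat <- logistic_weight(t, cf[["k"]], cf[["a"]], cf[["b"]])
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - sse / sst
  structure(
    list(k = cf[["k"]], a = cf[["a"]], b = cf[["b"]],
         r2 = r2, adequate = r2 > r2_adequate, n = length(t),
         fitted = yhat, residuals = y - yhat),
    class = "logistic_fit"
  )
}

# Log-linearisation start plus a coarse grid fallback.
.logistic_starts <- function(t, y) {
  starts <- list()
  k0 <- 1.05 * max(y)
  z <- k0 / pmax(y, 1e-8) - 1
  ok <- z > 0
  if (sum(ok) >= 2) {
    cf <- stats::coef(stats::lm(log(z[ok]) ~ t[ok]))
    b0 <- -cf[[2]]
    a0 <- exp(cf[[1]])
    if (is.finite(a0) && is.finite(b0) && a0 > 0 && b0 > 0) {
      starts[[length(starts) + 1L]] <- list(k = k0, a = a0, b = b0)
    }
  }
  span <- diff(range(t))
  for (kf in c(1.02, 1.1, 1.3)) {
    for (a0 in c(5, 20, 50)) {
      for (b0 in c(1, 3, 6) / span) {
        starts[[length(starts) + 1L]] <- list(k = kf * max(y), a = a0, b = b0)
      }
    }
  }
  starts
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "<logistic_fit> k=%.3f g, a=%.3f, b=%.4f /d, R2=%.4f (%s)\n",
    x$k, x$a, x$b, x$r2, if (x$adequate) "adequate" else "inadequate"
  ))
  invisible(x)
}

#' Instantaneous grain-filling rate
#'
#' The derivative of the logistic weight curve,
#' `V(t) = k a b exp(-b t) / (1 + a exp(-b t))^2`, in grams per day.
#' Positive for all finite `t`, vanishing in both tails, and maximal at
#' the inflection `t* = ln(a)/b` where it equals `k b / 4`.
#'
#' @param fit A [fit_logistic()] result, or a list with `k`, `a`, `b`.
#' @param t Days (numeric vector).
#' @return Filling rate, g/day.
#' @export
filling_rate <- function(fit, t) {
  e <- fit$a * exp(-fit$b * t)
  fit$k * fit$b * e / (1 + e)^2
}

#' Derived grain-filling parameters
#'
#' From fitted `(k, a, b)`:
#' \describe{
#'   \item{`c0`}{initial grain weight at the first sampling day,
#'     `k/(1 + a)` (g);}
#'   \item{`vmax`}{maximum filling rate, `k b / 4` (g/d), attained at the
#'     inflection of the curve;}
#'   \item{`vmean`}{mean filling rate over the active period,
#'     `k b / 6` (g/d);}
#'   \item{`d`}{active filling period, `6 / b` (d) — the unique duration
#'     for which `vmean = k / d`;}
#'   \item{`t_end`}{filling end time: the day the curve reaches 96% of
#'     its ceiling, `t_end = ln(24 a) / b` from solving
#'     `y(t) = 0.96 k` (d);}
#'   \item{`v_late`}{late filling rate `V(t_end)` (g/d);}
#'   \item{`y_late`}{late grain accumulation (g): by default the weight
#'     accumulated by `t_end`, `y(t_end) = 0.96 k`; with
#'     `y_definition = "remaining"` the weight still to accumulate,
#'     `k - y(t_end) = 0.04 k`.}
#' }
#'
#' @param fit A [fit_logistic()] result, or a list with `k`, `a`, `b`.
#' @param y_definition Which reading of "late grain accumulation" to
#'   report as `y_late`; both are returned, this picks the default.
#' @return Named list `c0`, `vmax`, `vmean`, `d`, `t_end`, `v_late`,
#'   `y_late`, `y_at_t`, `y_remaining`.
#' @export
derive_filling_parameters <- function(fit,
                                      y_definition = c("at_T", "remaining")) {
  y_definition <- match.arg(y_definition)
  k <- fit$k; a <- fit$a; b <- fit$b
  stopifnot(k > 0, a > 0, b > 0)
  t_end <- log(24 * a) / b   # y(t_end) = 0.96 k, since 100/96 - 1 = 1/24
  y_at_t <- logistic_weight(t_end, k, a, b)
  res <- list(
    c0 = k / (1 + a),
    vmax = k * b / 4,
    vmean = k * b / 6,
    d = 6 / b,
    t_end = t_end,
    v_late = filling_rate(fit, t_end),
    y_at_t = y_at_t,
    y_remaining = k - y_at_t
  )
  res$y_late <- if (y_definition == "at_T") res$y_at_t else res$y_remaining
  res
}

#' Fit the filling model to every line of a series table
#'
#' @param series Data frame `line`, `t_days`, `tgw_g` (long format, as
#'   written by [make_filling_series()]).
#' @param y_definition Passed to [derive_filling_parameters()].
#' @param r2_adequate Passed to [fit_logistic()].
#' @return Data frame with one row per line: `line`, `k`, `a`, `b`, `r2`,
#'   `adequate`, `c0`, `vmax`, `vmean`, `d`, `t_end`, `v_late`, `y_late`.
#' @export
fit_filling_table <- function(series, y_definition = "at_T",
                              r2_adequate = 0.95) {
  series <- as.data.frame(series)
  out <- do.call(rbind, lapply(split(series, series$line), function(g) {
    g <- g[order(g$t_days), ]
    f <- fit_logistic(g$t_days, g$tgw_g, r2_adequate = r2_adequate)
    dp <- derive_filling_parameters(f, y_definition = y_definition)
    data.frame(line = g$line[1], k = f$k, a = f$a, b = f$b, r2 = f$r2,
               adequate = f$adequate, c0 = dp$c0, vmax = dp$vmax,
               vmean = dp$vmean, d = dp$d, t_end = dp$t_end,
               v_late = dp$v_late, y_late = dp$y_late,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$line), ]
}
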