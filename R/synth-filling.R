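#' Logistic grain-weight curve
#'
#' The logistic accumulation model for thousand-grain dry weight,
#' `y(t) = k / (1 + a * exp(-b * t))`, with `t` in days since the first
#' sampling date (27 days after anthesis) and `y` in grams.  `k` is the
#' theoretical maximum thousand-grain weight; `a` and `b` shape the onset
#' and steepness of accumulation.
#'
#' @param t Days since first sampling (numeric vector).
#' @param k,a,b Model parameters, all strictly positive.
#' @return Thousand-grain weight in grams.
#' @export
logistic_weight <- function(t, k, a, b) {
  k / (1 + a * exp(-b * t))
}

#' Specify synthetic grain-filling series
#'
#' True per-line logistic parameters plus the sampling schedule and
#' measurement noise for generating thousand-grain-weight series.
#'
#' @param k,a,b Numeric vectors (recycled to a common length, one entry
#'   per line) of true parameters; all must be strictly positive.
#' @param days Sampling days, strictly increasing, with day 0 at 27 days
#'   after anthesis.  The default follows a typical filling-period field
#'   campaign of seven sampling dates spanning ~25 days.
#' @param noise_sd Additive Gaussian measurement noise, grams.
#' @param seed Integer seed.
#' @param line_ids Optional line labels.
#' @return An object of class `filling_spec`.
#' @export
filling_spec <- function(k, a, b, days = c(0, 2, 6, 8, 12, 16, 25),
                         noise_sd = 0.5, seed = 1L, line_ids = NULL) {
  n <- max(length(k), length(a), length(b))
  k <- rep_len(k, n); a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(k <= 0) || any(a <= 0) || any(b <= 0)) {
    stop("logistic parameters k, a, b must all be > 0", call. = FALSE)
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("`days` must be strictly increasing", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (is.null(line_ids)) line_ids <- sprintf("L%02d", seq_len(n))
  structure(
    list(k = k, a = a, b = b, line_ids = line_ids,
         days = as.numeric(days), noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "filling_spec"
  )
}

#' Generate thousand-grain-weight series
#'
#' Evaluates the logistic curve at the sampling days for each line and
#' adds Gaussian measurement noise.  With `noise_sd = 0` the series
#' reproduces the model to machine precision.  Noisy weights are
#' truncated at zero: a measured dry mass cannot be negative.
#'
#' @param spec A [filling_spec()].
#' @return Data frame `line`, `t_days`, `tgw_g` (long format, CSV-ready).
#' @export
make_filling_series <- function(spec) {
  stopifnot(inherits(spec, "filling_spec"))
  n <- length(spec$k); nd <- length(spec$days)
  out <- data.frame(
    line = rep(spec$line_ids, each = nd),
    t_days = rep(spec$days, n),
    tgw_g = unlist(lapply(seq_len(n), function(i) {
      logistic_weight(spec$days, spec$k[i], spec$a[i], spec$b[i])
    })),
    stringsAsFactors = FALSE
  )
  if (spec$noise_sd > 0) {
    out$tgw_g <- pmax(0, out$tgw_g +
      withr::with_seed(spec$seed,
                       stats::rnorm(nrow(out), 0, spec$noise_sd)))
  }
  out
}
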