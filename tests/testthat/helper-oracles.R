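# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: plain loops, closed forms and base-R
# optimisers only.

# Brute-force per-pixel plot mean over half-open 0-based bounds.
brute_plot_mean <- function(px, mask, row0, row1, col0, col1) {
  tot <- 0; n <- 0L
  for (r in (row0 + 1):row1) {
    for (cc in (col0 + 1):col1) {
      v <- px[r, cc]
      if (!is.nan(v) && !mask[r, cc]) {
        tot <- tot + v
        n <- n + 1L
      }
    }
  }
  tot / n
}

# Brute-force neighbour normalization over the adjacency list, plot
# level, then line averaging -- an explicit double loop.
brute_normalize <- function(ct, adjacency) {
  out <- data.frame()
  for (s in unique(ct$season)) {
    for (d in unique(ct$date[ct$season == s])) {
      g <- ct[ct$season == s & ct$date == d, ]
      g$rel <- NA_real_
      for (i in seq_len(nrow(g))) {
        nb <- adjacency[[g$plot_id[i]]]
        vals <- g$ct_mean[match(nb, g$plot_id)]
        vals <- vals[!is.na(vals)]
        g$rel[i] <- g$ct_mean[i] - mean(vals)
      }
      for (ln in unique(g$line)) {
        out <- rbind(out, data.frame(
          line = ln, season = s, date = d,
          rel_ct = mean(g$rel[g$line == ln])))
      }
    }
  }
  out
}

# Closed-form OLS slope.
ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Grid search + Nelder-Mead refinement for the logistic fit, independent
# of Levenberg-Marquardt and of the package's initialisation.
grid_logistic <- function(t, y) {
  sse <- function(p) sum((y - p[1] / (1 + p[2] * exp(-p[3] * t)))^2)
  best <- NULL; best_sse <- Inf
  for (k in max(y) * c(1.0, 1.02, 1.05, 1.1, 1.2, 1.4)) {
    for (a in c(2, 5, 10, 20, 40, 80)) {
      for (b in seq(0.05, 0.6, by = 0.05)) {
        s <- sse(c(k, a, b))
        if (s < best_sse) { best_sse <- s; best <- c(k, a, b) }
      }
    }
  }
  fit <- stats::optim(best, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  fit <- stats::optim(fit$par, sse, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  list(k = fit$par[1], a = fit$par[2], b = fit$par[3], sse = fit$value)
}

# Pearson r and its t-test p from the covariance formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE))
}

# A small two-season synthetic trial reused by several tests.
demo_field <- function(noise_sd = 0, seed = 7L, ...) {
  spec <- typed_field_spec(3, 3, 2, grid = c(4, 6), plot_px = 8,
                           noise_sd = noise_sd, seed = seed, ...)
  s1 <- make_thermal_frames(spec, dates = c(0, 4, 7, 10, 17), season = "S1")
  s2 <- make_thermal_frames(spec, dates = c(0, 4, 7, 10, 17), season = "S2")
  ct <- rbind(extract_ct_frames(s1$frames, s1$layout),
              extract_ct_frames(s2$frames, s2$layout))
  list(spec = spec, s1 = s1, s2 = s2, ct = ct, layout = s1$layout)
}
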