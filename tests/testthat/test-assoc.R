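test_that("exact linear dependence gives r = +-1 with *** at n >= 5", {
  x <- 1:8
  tab <- data.frame(x = x, y = 2 * x + 3, z = -x)
  pan <- correlation_panel(tab, c("x", "y", "z"))
  cell <- function(a, b) pan[pan$var1 == a & pan$var2 == b, ]
  expect_equal(cell("x", "y")$r, 1)
  expect_equal(cell("x", "y")$star, "***")
  expect_equal(cell("x", "z")$r, -1)
  expect_equal(cell("x", "x")$r, 1)
})

test_that("panel r and p match the closed-form oracle", {
  withr::with_seed(103L, {
    tab <- data.frame(u = rnorm(20), v = rnorm(20))
    tab$w <- 0.6 * tab$u + 0.8 * rnorm(20)
    pan <- correlation_panel(tab, c("u", "v", "w"))
    for (pr in list(c("u", "v"), c("u", "w"), c("v", "w"))) {
      o <- pearson_oracle(tab[[pr[1]]], tab[[pr[2]]])
      cell <- pan[pan$var1 == pr[1] & pan$var2 == pr[2], ]
      expect_equal(cell$r, o$r, tolerance = 1e-12)
      expect_equal(cell$p, o$p, tolerance = 1e-12)
    }
  })
})

test_that("panel is symmetric, affine-invariant, stars track p", {
  withr::with_seed(107L, {
    tab <- data.frame(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    tab$b <- tab$b + 0.9 * tab$a
    pan <- correlation_panel(tab, c("a", "b", "c"))
    # symmetry + unit diagonal
    for (i in seq_len(nrow(pan))) {
      mirror <- pan[pan$var1 == pan$var2[i] & pan$var2 == pan$var1[i], ]
      expect_equal(pan$r[i], mirror$r)
    }
    expect_equal(pan$r[pan$var1 == pan$var2], rep(1, 3))
    # positive affine maps leave r untouched
    tab2 <- transform(tab, a = 3 * a + 7, b = 0.5 * b - 2)
    pan2 <- correlation_panel(tab2, c("a", "b", "c"))
    expect_equal(pan2$r, pan$r, tolerance = 1e-12)
    # star assignment is a pure function of p
    expect_identical(pan$star, star_for_p(pan$p))
    thr <- c("***" = 0.001, "**" = 0.01, "*" = 0.05)
    starred <- pan$star %in% names(thr)
    expect_true(all(pan$p[starred] < thr[pan$star[starred]]))
  })
})

test_that("zero-variance and short columns yield undefined cells", {
  tab <- data.frame(x = c(1, 2, 3, 4), y = c(2, 2, 2, 2),
                    z = c(1, NA, NA, NA))
  pan <- correlation_panel(tab, c("x", "y", "z"))
  expect_true(is.na(pan$r[pan$var1 == "x" & pan$var2 == "y"]))
  expect_true(is.na(pan$r[pan$var1 == "x" & pan$var2 == "z"]))
})

test_that("strong planted CT-Pn correlation reproduces a *** negative cell", {
  ct <- data.frame(line = sprintf("L%02d", 1:60),
                   rel_ct = withr::with_seed(5L, rnorm(60)))
  spec <- trait_spec(data.frame(trait = "Pn", mean = 20, sd = 3,
                                r_ct = -0.9), seed = 109L)
  tab <- make_trait_table(spec, ct)
  pan <- correlation_panel(tab, c("rel_ct", "Pn"))
  cell <- pan[pan$var1 == "rel_ct" & pan$var2 == "Pn", ]
  expect_lt(cell$r, 0)
  expect_equal(cell$star, "***")
})

test_that("group contrast arithmetic and letter display behave", {
  tab <- data.frame(line = sprintf("L%02d", 1:12),
                    Pn = c(rep(12, 6), rep(10, 6)))
  calls <- data.frame(line = tab$line,
                      call = rep(c("cold", "warm"), each = 6))
  # zero within-group variance: degenerate, but arithmetic must hold
  tab$Pn <- tab$Pn + withr::with_seed(113L, rnorm(12, 0, 0.3))
  ctr <- group_contrast(tab, calls, "Pn")
  m <- ctr$means
  expect_equal(ctr$diff,
               m$mean[m$group == "cold"] - m$mean[m$group == "warm"])
  expect_equal(ctr$pct_diff, 100 * ctr$diff / m$mean[m$group == "warm"])

  # identical groups: no significant difference, shared letter
  tab2 <- data.frame(line = tab$line, Pn = rep(c(9, 10, 11), 4))
  ctr2 <- group_contrast(tab2, calls, "Pn")
  expect_gt(ctr2$p, 0.05)
  expect_equal(abs(ctr2$pct_diff), 0)
  expect_equal(unique(ctr2$means$letter), "a")

  # cold mean 12, warm mean 10 -> +20.0%
  tab3 <- data.frame(line = tab$line, Pn = rep(c(12, 10), each = 6))
  expect_warning(ctr3 <- group_contrast(tab3, calls, "Pn"), NA)
  expect_equal(ctr3$pct_diff, 20)

  # a singleton group reports the difference but skips the test
  calls4 <- calls; calls4$call[1:5] <- "warm"
  expect_warning(ctr4 <- group_contrast(tab3, calls4, "Pn"), "size 1")
  expect_true(is.na(ctr4$p))
})

test_that("Welch rejection rate tracks the power oracle", {
  # shifted groups (delta = 1 sd, n = 30): simulate the rejection rate
  # and compare against power.t.test; Welch on equal variances is close
  # to the pooled test, so the analytic power is the reference
  n <- 30; reps <- 400
  rej <- withr::with_seed(127L, {
    mean(replicate(reps, {
      t.test(rnorm(n), rnorm(n, 1))$p.value < 0.05
    }))
  })
  pow <- power.t.test(n = n, delta = 1, sd = 1, sig.level = 0.05)$power
  mc_se <- sqrt(pow * (1 - pow) / reps)
  expect_lt(abs(rej - pow), 4 * mc_se)
})

test_that("dry-matter deltas are later-minus-earlier, per organ", {
  w <- expand.grid(line = c("L1", "L2"), organ = c("spike", "stem"),
                   dap = c(27, 33), stringsAsFactors = FALSE)
  w$weight_g <- c(30, 28, 12, 11, 41.5, 39, 15, 13)
  dd <- dry_matter_delta(w)
  expect_equal(dd$delta_g[dd$line == "L1" & dd$organ == "spike"], 11.5)
  # equal weights -> zero
  w0 <- w; w0$weight_g[w0$dap == 33] <- w0$weight_g[w0$dap == 27]
  expect_true(all(dry_matter_delta(w0)$delta_g == 0))
  # random table equals row-wise recomputation
  set.seed(131)
  w$weight_g <- runif(8, 5, 50)
  dd <- dry_matter_delta(w)
  for (i in seq_len(nrow(dd))) {
    expect_equal(
      dd$delta_g[i],
      w$weight_g[w$line == dd$line[i] & w$organ == dd$organ[i] & w$dap == 33] -
        w$weight_g[w$line == dd$line[i] & w$organ == dd$organ[i] & w$dap == 27]
    )
  }
  # a missing date skips the line with a warning
  expect_warning(dry_matter_delta(w[-1, ]), "skipped")
})

test_that("weather summaries: totals, fractions and edge cases", {
  w <- make_weather(rep(2, 10), rep(20, 10))
  s <- weather_summary(w, c(1, 10))
  expect_equal(s$fraction_pct, 100)
  # single nonzero day: the window total is that day
  w2 <- make_weather(c(0, 0, 7.5, 0), rep(20, 4))
  expect_equal(weather_summary(w2, c(3, 3))$window_mm, 7.5)
  # disjoint windows partition the period total
  set.seed(137)
  w3 <- make_weather(round(runif(30, 0, 20), 1), rep(20, 30))
  parts <- weather_summary(w3, c(1, 9))$window_mm +
    weather_summary(w3, c(10, 21))$window_mm +
    weather_summary(w3, c(22, 30))$window_mm
  expect_equal(parts, weather_summary(w3, c(1, 30))$period_mm)
  # dry period: fraction undefined
  expect_true(is.na(weather_summary(make_weather(c(0, 0), c(1, 2)),
                                    c(1, 2))$fraction_pct))
})
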