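test_that("noiseless series recover exact parameters with R2 = 1", {
  t <- seq(0, 24, 3)
  y <- logistic_weight(t, 45, 20, 0.25)
  f <- fit_logistic(t, y)
  expect_equal(f$k, 45, tolerance = 1e-6)
  expect_equal(f$a, 20, tolerance = 1e-6)
  expect_equal(f$b, 0.25, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_true(f$adequate)
})

test_that("degenerate series are rejected, not silently fitted", {
  expect_error(fit_logistic(c(0, 3, 6, 9), rep(5, 4)), "constant")
  expect_error(fit_logistic(c(0, 3, 6), c(1, 2, 3)), "4 observations")
  expect_error(fit_logistic(c(0, 3, 3, 9), 1:4), "increasing")
  expect_error(fit_logistic(c(0, 3, 6, 9), c(1, -2, 3, 4)), ">= 0")
})

test_that("clearly non-sigmoid data fail the R2 > 0.95 screen", {
  # strictly concave-down data cannot be matched by a rising logistic
  t <- seq(0, 24, 3)
  y <- 40 - (t - 12)^2 / 6
  f <- fit_logistic(t, y)
  expect_false(f$adequate)
  expect_lt(f$r2, 0.95)
})

test_that("noisy fits agree with the grid-search + refinement oracle", {
  t <- c(0, 2, 6, 8, 12, 16, 25)
  withr::with_seed(83L, {
    for (i in 1:5) {
      k <- runif(1, 35, 55); a <- runif(1, 10, 30); b <- runif(1, 0.15, 0.35)
      y <- logistic_weight(t, k, a, b) + rnorm(length(t), 0, 0.5)
      f <- fit_logistic(t, pmax(y, 0))
      o <- grid_logistic(t, pmax(y, 0))
      expect_equal(f$k, o$k, tolerance = 1e-3)
      expect_equal(f$a, o$a, tolerance = 1e-3)
      expect_equal(f$b, o$b, tolerance = 1e-3)
    }
  })
})

test_that("filling rate evaluates the derivative identities", {
  fit <- list(k = 40, a = 19, b = 0.2)
  expect_equal(filling_rate(fit, 0), 40 * 19 * 0.2 / 400)
  # at the inflection t* = ln(a)/b the rate is kb/4
  tstar <- log(19) / 0.2
  expect_equal(filling_rate(fit, tstar), 40 * 0.2 / 4, tolerance = 1e-12)
  # positive everywhere, vanishing in the tails
  expect_true(all(filling_rate(fit, seq(-50, 120, 0.5)) > 0))
  expect_lt(filling_rate(fit, 1e4), 1e-12)
})

test_that("vmax equals the numeric maximum of the rate curve", {
  withr::with_seed(89L, {
    for (i in 1:25) {
      fit <- list(k = runif(1, 30, 60), a = runif(1, 5, 50),
                  b = runif(1, 0.1, 0.5))
      num <- optimize(function(t) filling_rate(fit, t),
                      interval = c(-50, 150), maximum = TRUE,
                      tol = 1e-12)$objective
      expect_equal(fit$k * fit$b / 4, num, tolerance = 1e-8)
    }
  })
})

test_that("derived parameters match their defining equations", {
  dp <- derive_filling_parameters(list(k = 40, a = 19, b = 0.2))
  expect_equal(dp$c0, 2.0)
  dp2 <- derive_filling_parameters(list(k = 60, a = 19, b = 0.3))
  expect_equal(dp2$vmax, 4.5)
  expect_equal(dp2$vmean, 3.0)
  expect_equal(dp2$vmax / dp2$vmean, 1.5)
  # filling end time: closed form vs root-bracketing oracle on y(T)=0.96k
  fit <- list(k = 45, a = 20, b = 0.25)
  dp3 <- derive_filling_parameters(fit)
  root <- uniroot(function(t) logistic_weight(t, 45, 20, 0.25) - 0.96 * 45,
                  c(0, 200), tol = 1e-12)$root
  expect_equal(dp3$t_end, root, tolerance = 1e-8)
  expect_equal(dp3$t_end, 24.695, tolerance = 1e-4)
  expect_equal(dp3$y_at_t, 0.96 * 45, tolerance = 1e-10)
  expect_equal(dp3$y_remaining, 0.04 * 45, tolerance = 1e-10)
  expect_equal(dp3$v_late, filling_rate(fit, root), tolerance = 1e-8)
  # the alternative reading of late accumulation is selectable
  alt <- derive_filling_parameters(fit, y_definition = "remaining")
  expect_equal(alt$y_late, alt$y_remaining)
})

test_that("fitted curves are strictly increasing in t", {
  withr::with_seed(97L, {
    t <- c(0, 2, 6, 8, 12, 16, 25)
    y <- logistic_weight(t, 48, 15, 0.2) + rnorm(7, 0, 0.5)
    f <- fit_logistic(t, pmax(y, 0))
    grid <- seq(-10, 60, 0.25)
    expect_true(all(diff(logistic_weight(grid, f$k, f$a, f$b)) > 0))
  })
})

test_that("fit_filling_table fits every line and flags adequacy", {
  fs <- filling_spec(k = c(40, 50), a = c(15, 25), b = c(0.2, 0.3),
                     noise_sd = 0.5, seed = 101L)
  tab <- fit_filling_table(make_filling_series(fs))
  expect_equal(nrow(tab), 2L)
  expect_true(all(c("k", "a", "b", "r2", "adequate", "c0", "vmax", "vmean",
                    "d", "t_end", "v_late", "y_late") %in% names(tab)))
  expect_equal(tab$vmax / tab$vmean, c(1.5, 1.5))
  expect_equal(tab$d, 6 / tab$b)
})
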