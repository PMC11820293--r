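test_that("uniform fields normalize to zero; simple offsets are exact", {
  # all plots at 30 -> every relative CT 0
  fld <- make_thermal_frames(field_spec(6, 2, grid = c(3, 4), noise_sd = 0,
                                        offsets = rep(5, 6), slopes = 0,
                                        seed = 5L),
                             dates = 0, season = "S1")
  ct <- extract_ct(fld$frames[[1]], fld$layout)
  rel <- normalize_ct(ct, fld$layout)
  expect_equal(rel$rel_ct, rep(0, nrow(rel)), tolerance = 1e-12)

  # one target at 30, all six neighbours at 29.5 -> +0.5
  plots <- data.frame(
    plot_id = sprintf("P%d", 1:7), line_id = sprintf("L%d", 1:7),
    replicate = 1L,
    row0 = 0L, row1 = 2L, col0 = seq(0L, 18L, 3L), col1 = seq(2L, 20L, 3L)
  )
  adj <- c(list(P1 = sprintf("P%d", 2:7)),
           setNames(lapply(2:7, function(i) "P1"), sprintf("P%d", 2:7)))
  lay <- plot_layout(plots, adj, c(2, 20))
  ct <- data.frame(line = plots$line_id, season = "S1", date = 0,
                   replicate = 1L, plot_id = plots$plot_id,
                   ct_mean = c(30, rep(29.5, 6)))
  rel <- normalize_ct(ct, lay)
  expect_equal(rel$rel_ct[rel$line == "L1"], 0.5)
})

test_that("normalization matches the brute-force adjacency-loop oracle", {
  fld <- demo_field(noise_sd = 0.3, seed = 37L)
  rel <- normalize_ct(fld$ct, fld$layout)
  oracle <- brute_normalize(fld$ct, fld$layout$adjacency)
  key <- paste(rel$line, rel$season, rel$date)
  ok <- paste(oracle$line, oracle$season, oracle$date)
  expect_equal(rel$rel_ct, oracle$rel_ct[match(key, ok)], tolerance = 1e-12)
})

test_that("relative CT is invariant to a global per-date offset", {
  fld <- demo_field(noise_sd = 0.3, seed = 43L)
  rel1 <- normalize_ct(fld$ct, fld$layout)
  ct2 <- fld$ct
  for (d in unique(ct2$date)) {
    ct2$ct_mean[ct2$date == d] <- ct2$ct_mean[ct2$date == d] + 3.7 * (d + 1)
  }
  rel2 <- normalize_ct(ct2, fld$layout)
  expect_equal(rel2$rel_ct, rel1$rel_ct, tolerance = 1e-10)
})

test_that("mean relative CT per date is near zero on the default grid", {
  fld <- demo_field(noise_sd = 0.2, seed = 53L)
  rel <- normalize_ct(fld$ct, fld$layout)
  daily <- aggregate(rel_ct ~ season + date, data = rel, FUN = mean)
  expect_true(all(abs(daily$rel_ct) < 0.1))
})

test_that("both normalization orders run and agree on balanced fields", {
  fld <- demo_field(noise_sd = 0, seed = 59L)
  p <- normalize_ct(fld$ct, fld$layout, order = "plot")
  l <- normalize_ct(fld$ct, fld$layout, order = "line")
  expect_equal(dim(p), dim(l))
  # noiseless: plot CT already equals its line value, orders coincide on
  # the target term; neighbour means differ only via replicate identity
  expect_equal(p$rel_ct, l$rel_ct, tolerance = 1e-10)
})

test_that("isolated plots error; absent neighbours drop with a warning", {
  plots <- data.frame(
    plot_id = c("P1", "P2", "P3"), line_id = c("L1", "L2", "L3"),
    replicate = 1L, row0 = 0L, row1 = 2L,
    col0 = c(0L, 3L, 6L), col1 = c(2L, 5L, 8L)
  )
  lay <- plot_layout(plots, list(P1 = "P2", P2 = "P1", P3 = character()),
                     c(2, 8))
  ct <- data.frame(line = plots$line_id, season = "S1", date = 0,
                   replicate = 1L, plot_id = plots$plot_id,
                   ct_mean = c(30, 29, 31))
  expect_error(normalize_ct(ct, lay), "P3")

  lay2 <- plot_layout(plots, list(P1 = c("P2", "P3"), P2 = "P1",
                                  P3 = "P1"), c(2, 8))
  expect_warning(rel <- normalize_ct(ct[ct$plot_id != "P3", ], lay2),
                 "P3")
  expect_equal(rel$rel_ct[rel$line == "L1"], 30 - 29)
})

test_that("season offset check recovers a constant between-year shift", {
  fld <- demo_field(noise_sd = 0, seed = 61L)
  ct <- fld$ct
  # identical seasons -> all differences zero
  ct0 <- ct; ct0$ct_mean[ct0$season == "S2"] <-
    ct0$ct_mean[ct0$season == "S1"]
  expect_equal(season_offset_check(ct0)$diff, rep(0, 5))
  # season 2 = season 1 + 1.5 everywhere -> all differences 1.5
  ct1 <- ct; ct1$ct_mean[ct1$season == "S2"] <-
    ct1$ct_mean[ct1$season == "S1"] + 1.5
  expect_equal(season_offset_check(ct1)$diff, rep(1.5, 5))
})

test_that("season offset check recovers the generator's global offset", {
  # equal slopes across seasons isolate the ambient difference
  spec <- field_spec(8, 3, grid = c(4, 6), noise_sd = 0.15,
                     slopes = -0.05, seed = 67L)
  s1 <- make_thermal_frames(spec, dates = c(0, 4, 7), season = "S1")
  s2 <- make_thermal_frames(spec, dates = c(0, 4, 7), season = "S2")
  ct <- rbind(extract_ct_frames(s1$frames, s1$layout),
              extract_ct_frames(s2$frames, s2$layout))
  offs <- season_offset_check(ct)
  truth <- unname(spec$ambient["S2"] - spec$ambient["S1"])
  expect_equal(offs$diff, rep(truth, 3), tolerance = 0.05)

  # unpaired dates are excluded with a warning
  expect_warning(
    got <- season_offset_check(ct[!(ct$season == "S2" & ct$date == 7), ]),
    "only one season"
  )
  expect_equal(got$date, c(0, 4))
})
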