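#!/usr/bin/env Rscript
# Stage 1 -- simulate the two-season thermal trial with known ground truth.
#
# A 20-line wheat panel (7 planted cold-type, 7 warm-type, 6 mediate-type)
# in 3 replicate plots each on a 6x10 planting grid, imaged on five dates
# per season.  Season 2 is globally 1.5 C warmer.  Also generates the
# thousand-grain-weight series for every line and the rainy-season
# weather table.

suppressPackageStartupMessages(library(thermofill))

out <- "results/run"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 2026L

fspec <- typed_field_spec(7, 7, 6, noise_sd = 0.2, seed = seed)
dates <- c(0, 4, 7, 10, 17)
for (season in c("S1", "S2")) {
  fld <- make_thermal_frames(fspec, dates = dates, season = season)
  for (fr in fld$frames) {
    write_frame(fr, file.path(out, sprintf("frame_%s_d%02d.tif",
                                           fr$season, fr$date)))
  }
  if (season == "S1") {
    write_layout(fld$layout, file.path(out, "layout.yaml"))
    truth1 <- fld$truth
  } else {
    truth <- rbind(truth1, fld$truth)
    write.csv(truth, file.path(out, "truth_ct.csv"), row.names = FALSE)
  }
}
write.csv(data.frame(line = names(fspec$truth_type),
                     type = unname(fspec$truth_type)),
          file.path(out, "truth_types.csv"), row.names = FALSE)

filspec <- withr::with_seed(seed + 11L, filling_spec(
  k = runif(20, 35, 55), a = runif(20, 10, 30), b = runif(20, 0.15, 0.35),
  noise_sd = 0.5, seed = seed + 12L
))
write.csv(make_filling_series(filspec), file.path(out, "filling.csv"),
          row.names = FALSE)
write.csv(data.frame(line = filspec$line_ids, k = filspec$k,
                     a = filspec$a, b = filspec$b),
          file.path(out, "truth_filling.csv"), row.names = FALSE)

rf <- demo_rainfall()
write_weather(rf$weather, file.path(out, "weather.csv"))

message("Simulated: 10 frames (", paste(dim(read_frame(
  file.path(out, "frame_S1_d00.tif"))$pixels), collapse = "x"),
  " px), 60 plots, 20 filling series, 46-day weather record -> ", out)
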