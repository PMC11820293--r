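#' Configuration for an end-to-end pipeline run
#'
#' Bundles every knob of the demo pipeline: the synthetic field design,
#' seeding, the soil-mask threshold, the typing tolerance, and the
#' toggles for the genuinely open analysis choices (normalization order,
#' the reading of "late grain accumulation", optional Benjamini-Hochberg
#' correction).
#'
#' @param out_dir Output directory; created if absent.
#' @param seed Integer master seed; every stochastic stage derives its
#'   stream from it, so identical configs give byte-identical outputs.
#' @param n_cold,n_warm,n_mediate Planted lines per temperature type.
#' @param grid Planting grid `c(rows, cols)`; keep it dense enough that
#'   no plot is isolated from neighbours.
#' @param dates Measurement day indices shared by the two seasons.
#' @param noise_sd Thermal sensor noise sd, degrees C.
#' @param mask_threshold Soil-mask temperature threshold, degrees C
#'   (`NULL` disables masking; the default masks soil sitting ~8 degrees
#'   above canopy).
#' @param epsilon Typing slope tolerance, degrees C/day.
#' @param norm_order Normalization order (`"plot"` or `"line"`), see
#'   [normalize_ct()].
#' @param y_definition Reading of late grain accumulation, see
#'   [derive_filling_parameters()].
#' @param p_adjust `"none"` or `"BH"` for correlation panels.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       n_cold = 7L, n_warm = 7L, n_mediate = 6L,
                       grid = c(6L, 10L),
                       dates = c(0, 4, 7, 10, 17),
                       noise_sd = 0.2, mask_threshold = 31,
                       epsilon = 0.01, norm_order = "plot",
                       y_definition = "at_T", p_adjust = "none") {
  structure(
    list(out_dir = out_dir, seed = as.integer(seed),
         n_cold = n_cold, n_warm = n_warm, n_mediate = n_mediate,
         grid = as.integer(grid), dates = dates, noise_sd = noise_sd,
         mask_threshold = mask_threshold, epsilon = epsilon,
         norm_order = norm_order, y_definition = y_definition,
         p_adjust = p_adjust),
    class = "run_config"
  )
}

#' Run the whole pipeline on synthetic data
#'
#' Executes the six stages in order — simulate, extract, normalize,
#' classify, fit, associate — writing each stage's table under
#' `config$out_dir` and a `manifest.json` recording the seed, per-stage
#' row counts and MD5 hashes of every output, so a rerun with the same
#' config is verifiably identical.  Any stage error halts the run with
#' the stage name.
#'
#' @param config A [run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with all stage tables and the manifest.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, msg) if (!quiet) message("[", stage, "] ", msg)
  stage <- "simulate"
  res <- tryCatch({
    # -- simulate ---------------------------------------------------
    fspec <- typed_field_spec(config$n_cold, config$n_warm,
                              config$n_mediate, grid = config$grid,
                              noise_sd = config$noise_sd,
                              seed = config$seed)
    s1 <- make_thermal_frames(fspec, dates = config$dates, season = "S1")
    s2 <- make_thermal_frames(fspec, dates = config$dates, season = "S2")
    frame_paths <- character()
    for (fs in list(s1, s2)) {
      for (fr in fs$frames) {
        fp <- file.path(config$out_dir,
                        sprintf("frame_%s_d%02d.tif", fr$season, fr$date))
        write_frame(fr, fp)
        frame_paths <- c(frame_paths, fp)
      }
    }
    layout_path <- file.path(config$out_dir, "layout.yaml")
    write_layout(s1$layout, layout_path)
    truth <- rbind(s1$truth, s2$truth)
    utils::write.csv(truth, file.path(config$out_dir, "truth_ct.csv"),
                     row.names = FALSE)
    n_lines <- config$n_cold + config$n_warm + config$n_mediate
    filspec <- withr::with_seed(config$seed + 11L, filling_spec(
      k = stats::runif(n_lines, 35, 55),
      a = stats::runif(n_lines, 10, 30),
      b = stats::runif(n_lines, 0.15, 0.35),
      seed = config$seed + 12L
    ))
    filling <- make_filling_series(filspec)
    utils::write.csv(filling, file.path(config$out_dir, "filling.csv"),
                     row.names = FALSE)
    say(stage, paste(length(frame_paths), "frames,",
                     nrow(filling), "filling rows"))

    # -- extract ----------------------------------------------------
    stage <- "extract"
    layout <- read_layout(layout_path)
    frames <- c(
      lapply(s1$frames, function(f)
        read_frame(file.path(config$out_dir,
                             sprintf("frame_%s_d%02d.tif", f$season, f$date)),
                   date = f$date, season = f$season, meta = f$meta)),
      lapply(s2$frames, function(f)
        read_frame(file.path(config$out_dir,
                             sprintf("frame_%s_d%02d.tif", f$season, f$date)),
                   date = f$date, season = f$season, meta = f$meta))
    )
    ct <- extract_ct_frames(frames, layout,
                            mask_threshold = config$mask_threshold)
    utils::write.csv(ct, file.path(config$out_dir, "ct_raw.csv"),
                     row.names = FALSE)
    say(stage, paste(nrow(ct), "plot-date CT rows"))

    # -- normalize --------------------------------------------------
    stage <- "normalize"
    rel <- normalize_ct(ct, layout, order = config$norm_order)
    utils::write.csv(rel, file.path(config$out_dir, "ct_relative.csv"),
                     row.names = FALSE)
    offs <- season_offset_check(ct)
    say(stage, sprintf("%d line-date rows; mean S2-S1 offset %.2f C",
                       nrow(rel), mean(offs$diff)))

    # -- classify ---------------------------------------------------
    stage <- "classify"
    calls <- classify_lines(rel, epsilon = config$epsilon)
    utils::write.csv(calls, file.path(config$out_dir, "type_calls.csv"),
                     row.names = FALSE)
    say(stage, paste(table(calls$call)["cold"], "cold /",
                     table(calls$call)["warm"], "warm /",
                     table(calls$call)["mediate"], "mediate"))

    # -- fit --------------------------------------------------------
    stage <- "fit"
    fits <- fit_filling_table(filling, y_definition = config$y_definition)
    utils::write.csv(fits, file.path(config$out_dir, "filling_fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      fits, file.path(config$out_dir, "filling_fits.json"),
      dataframe = "rows", digits = NA
    )
    say(stage, sprintf("%d fits, min R2 %.4f", nrow(fits), min(fits$r2)))

    # -- associate --------------------------------------------------
    stage <- "associate"
    mean_rel <- stats::aggregate(rel_ct ~ line, data = rel, FUN = mean)
    tab <- merge(mean_rel, fits[, c("line", "vmax", "vmean", "d", "t_end")],
                 by = "line")
    tspec <- trait_spec(data.frame(
      trait = c("Pn", "Cond", "GPC"),
      mean = c(20, 0.4, 14), sd = c(3, 0.08, 1.5),
      r_ct = c(-0.7, -0.5, 0.4)
    ), seed = config$seed + 21L)
    tab <- make_trait_table(tspec, tab)
    panel <- correlation_panel(
      tab, c("rel_ct", "vmax", "vmean", "d", "t_end", "Pn", "Cond", "GPC"),
      p_adjust = config$p_adjust
    )
    utils::write.csv(panel, file.path(config$out_dir, "corr_panel.csv"),
                     row.names = FALSE)
    contr <- group_contrast(tab, calls, "Pn")
    utils::write.csv(
      data.frame(trait = "Pn", diff = contr$diff,
                 pct_diff = contr$pct_diff, p = contr$p),
      file.path(config$out_dir, "contrasts.csv"), row.names = FALSE
    )
    say(stage, sprintf("Pn cold-warm contrast %+.1f%%", contr$pct_diff))

    list(ct = ct, rel = rel, calls = calls, fits = fits, panel = panel,
         contrast = contr, truth = truth, layout = layout)
  }, error = function(e) {
    stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  outputs <- list.files(config$out_dir, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    seed = config$seed,
    stages = c("simulate", "extract", "normalize", "classify", "fit",
               "associate"),
    rows = list(ct_raw = nrow(res$ct), ct_relative = nrow(res$rel),
                type_calls = nrow(res$calls), filling_fits = nrow(res$fits),
                corr_panel = nrow(res$panel)),
    md5 = as.list(tools::md5sum(sort(outputs)))
  )
  names(manifest$md5) <- basename(sort(outputs))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  res$manifest <- manifest
  invisible(res)
}
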