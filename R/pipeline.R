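# End-to-end campaign pipeline: frames + logs + anchors -> per-tree fused
# table -> scaled dataset -> trained network -> PCA/correlation summaries.

#' Default pipeline configuration
#'
#' Returns the full parameter set with defaults; a YAML config file or an
#' override list replaces any subset. Paths: `rgb_frames`,
#' `thermal_frames`, `frames_srt` (camera GPS/timestamp sidecar), `enose`,
#' `track`, `anchors`, `weather` (optional).
#'
#' @param overrides Named list (possibly nested) of overrides.
#' @return Nested configuration list.
#' @export
default_config <- function(overrides = list()) {
  cfg <- list(
    paths = list(rgb_frames = NULL, thermal_frames = NULL, frames_srt = NULL,
                 enose = NULL, track = NULL, anchors = NULL, weather = NULL),
    rgb = list(grid_rows = 5L, grid_cols = 5L, large_gap_fraction = 0.75,
               k = 0.5, threshold = NULL),
    thermal = list(sky_cutoff = 0, p_wet = 5, p_dry = 95,
                   calib_gain = 160 / 16383, calib_offset = -40),
    geosync = list(rate_hz = 10, max_radius_m = 15),
    ann = list(enabled = TRUE, n_hidden = 20L, seed = 7L,
               max_epochs = 200L, val_fail_limit = 6L),
    stats = list(enabled = TRUE)
  )
  utils::modifyList(cfg, overrides)
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file; missing keys take their defaults from
#'   [default_config()].
#' @return Configuration list.
#' @export
read_config <- function(path) {
  default_config(yaml::read_yaml(path))
}

#' Run the full monitoring pipeline for one campaign
#'
#' Stages: (1) per-frame RGB cover metrics; (2) per-frame thermal water
#' status with ambient temperature taken from the nearest E-nose sample;
#' (3) track densification, geofencing and per-tree fusion of the RGB,
#' thermal and E-nose streams; (4) scaled dataset and network training
#' (when enough trees have complete records); (5) PCA and correlation
#' summaries. Every stage writes its table under `out_dir` and logs its
#' row count; empty-canopy frames and never-entered trees are logged and
#' skipped, not fatal.
#'
#' @param config Configuration list (see [default_config()]) or a YAML
#'   path.
#' @param out_dir Output run directory (created; existing files are
#'   overwritten).
#' @return Invisibly, a list with `per_tree`, `rgb`, `thermal`, `model`
#'   (or `NULL`), `fit` (or `NULL`), `pca`, `correlation`, `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  p <- config$paths
  for (key in c("rgb_frames", "thermal_frames", "frames_srt", "enose",
                "track", "anchors")) {
    if (is.null(p[[key]]) || !file.exists(p[[key]]))
      stop("config path '", key, "' missing or does not exist")
  }
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))

  enose <- read_enose_log(p$enose)
  logf("enose: %d samples", nrow(enose))

  frame_track <- read_srt_track(p$frames_srt)
  rgb <- analyze_rgb_dir(p$rgb_frames,
                         threshold = config$rgb$threshold,
                         grid_rows = config$rgb$grid_rows,
                         grid_cols = config$rgb$grid_cols,
                         large_gap_fraction = config$rgb$large_gap_fraction,
                         k = config$rgb$k)
  if (nrow(rgb) != nrow(frame_track))
    stop("frame sidecar has ", nrow(frame_track), " entries but ",
         nrow(rgb), " RGB frames were read")
  rgb$timestamp <- frame_track$timestamp
  logf("rgb: %d frames, %d with metrics", nrow(rgb), sum(!is.na(rgb$lai)))
  utils::write.csv(rgb, file.path(out_dir, "rgb_frames.csv"),
                   row.names = FALSE)

  th_frames <- read_thermal_frames(p$thermal_frames,
                                   gain = config$thermal$calib_gain,
                                   offset = config$thermal$calib_offset,
                                   timestamps = frame_track$timestamp)
  t_avg <- vapply(frame_track$timestamp, function(tt)
    enose$temp_C[which.min(abs(as.numeric(enose$timestamp) - as.numeric(tt)))],
    numeric(1))
  thermal <- analyze_thermal_frames(th_frames, t_average = t_avg,
                                    sky_cutoff = config$thermal$sky_cutoff,
                                    p_wet = config$thermal$p_wet,
                                    p_dry = config$thermal$p_dry)
  logf("thermal: %d frames analysed", nrow(thermal))
  utils::write.csv(thermal, file.path(out_dir, "thermal_frames.csv"),
                   row.names = FALSE)

  track <- read_srt_track(p$track)
  dense <- densify_track(track, rate_hz = config$geosync$rate_hz)
  anchors <- read_anchors(p$anchors)
  fences <- build_geofences(anchors,
                            max_radius_m = config$geosync$max_radius_m)
  intervals <- region_intervals(dense, fences)
  missed <- setdiff(anchors$tree_id, intervals$tree_id)
  if (length(missed)) logf("trees never entered: %s",
                           paste(missed, collapse = ", "))
  logf("geosync: %d interval(s) over %d tree(s)", nrow(intervals),
       length(unique(intervals$tree_id)))

  streams <- list(
    enose = enose[c("timestamp", ENOSE_CHANNELS, "temp_C", "rh_pct")],
    rgb = rgb[c("timestamp", "ff", "fc", "phi", "omega0", "lai", "laie")],
    thermal = thermal[c("timestamp", "t_canopy", "raw_index", "twsi",
                        "ig", "ctd")]
  )
  per_tree <- fuse_streams(streams, intervals)
  utils::write.csv(per_tree, file.path(out_dir, "per_tree.csv"),
                   row.names = FALSE)
  logf("fused: %d tree record(s)", nrow(per_tree))

  model <- NULL; fit <- NULL
  if (isTRUE(config$ann$enabled)) {
    ds <- tryCatch(build_scaled_dataset(per_tree), error = function(e) NULL)
    if (!is.null(ds) && nrow(ds$inputs) >= 10L) {
      ds <- split_dataset(ds, seed = config$ann$seed)
      model <- init_network(n_hidden = config$ann$n_hidden,
                            seed = config$ann$seed)
      model <- train_lm(model, ds, max_epochs = config$ann$max_epochs,
                        val_fail_limit = config$ann$val_fail_limit)
      fit <- fit_report(model, ds)
      save_network(model, file.path(out_dir, "model.json"))
      utils::write.csv(fit, file.path(out_dir, "fit_report.csv"),
                       row.names = FALSE)
      logf("ann: trained %d epoch(s); test R %.3f", model$epochs_run,
           fit$r[fit$stage == "test"])
    } else {
      logf("ann: skipped (fewer than 10 complete tree records)")
    }
  }

  pca <- NULL; corr <- NULL
  if (isTRUE(config$stats$enabled)) {
    num <- per_tree[vapply(per_tree, is.numeric, logical(1))]
    num <- num[!grepl("^n_", names(num))]
    num <- num[, colSums(!is.finite(as.matrix(num))) == 0, drop = FALSE]
    num <- num[, apply(num, 2L, stats::sd) > 0, drop = FALSE]
    if (nrow(num) >= 3L && ncol(num) >= 2L) {
      pca <- canopy_pca(num)
      corr <- pearson_matrix(num)
      export_stats(pca, corr, file.path(out_dir, "stats"))
      logf("stats: PCA PC1 %.1f%%, PC2 %.1f%%", pca$explained_pct[1],
           pca$explained_pct[2])
    } else {
      logf("stats: skipped (not enough complete variables)")
    }
  }

  invisible(list(per_tree = per_tree, rgb = rgb, thermal = thermal,
                 intervals = intervals, model = model, fit = fit,
                 pca = pca, correlation = corr, out_dir = out_dir))
}
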