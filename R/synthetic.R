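# Seed-deterministic synthetic generators: canopy RGB scenes with known
# cover/porosity, thermal frames with known canopy temperature, transect
# tracks with known pass times, and gas/physiology linked datasets with a
# known smooth mapping. Every generator records its ground truth so the
# pipeline can be tested end to end without field recordings.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are reproducible without disturbing the
#' session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Paint an ellipse (TRUE) onto a logical matrix, clipped to a pixel window.
paint_ellipse <- function(m, cy, cx, ry, rx, theta, rows, cols, value = TRUE) {
  rr <- max(min(rows), floor(cy - ry - rx)):min(max(rows), ceiling(cy + ry + rx))
  cc <- max(min(cols), floor(cx - ry - rx)):min(max(cols), ceiling(cx + ry + rx))
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  sub <- m[rr, cc, drop = FALSE]
  sub[inside] <- value
  m[rr, cc] <- sub
  m
}

#' Generate an upward canopy scene with known cover and porosity
#'
#' Builds a sky/canopy scene on the 5x5 analysis grid: grid cells are
#' filled with overlapping dark-green elliptical crown blobs until the
#' large-gap-based crown cover reaches `fc_target`, residual cover is
#' spread over partly-filled edge cells, and small circular holes are
#' punched inside crowns until porosity reaches `phi_target`. The realized
#' `ff`, `fc` and `phi` are bookkept from the true (noiseless) mask under
#' the same gap-analysis definitions the RGB pipeline uses, so recovery
#' can be judged against exactly what the scene presents.
#'
#' Sky renders bright blue (blue ~220) and canopy dark (blue ~60) with
#' Gaussian colour noise (sd 10), so valley thresholding is exercised
#' nontrivially. Crown blobs are clipped to their grid cell.
#'
#' @param fc_target Target crown cover in `[0, 0.98]`.
#' @param phi_target Target crown porosity in `[0.02, 0.7]`.
#' @param width,height Image size in pixels (default 512).
#' @param seed Integer seed.
#' @return List with `frame` (h x w x 3, 8-bit), `sky` (true logical mask,
#'   `TRUE` = sky), and `truth`: `fc_target`, `phi_target`, realized `ff`,
#'   `fc`, `phi`, `lai` (analytic from realized values), `seed`.
#' @export
gen_canopy_scene <- function(fc_target, phi_target, width = 512L,
                             height = 512L, seed = 1L) {
  if (fc_target > 0.98) stop("generator error: fc_target > 0.98 unreachable")
  stopifnot(fc_target >= 0, phi_target > 0, phi_target <= 0.7)
  h <- as.integer(height); w <- as.integer(width)
  sky <- matrix(TRUE, h, w)
  with_seed(seed, {
    if (fc_target > 0) {
      ri <- grid_cell_index(h, 5L)
      ci <- grid_cell_index(w, 5L)
      cell_rows <- split(seq_len(h), ri)
      cell_cols <- split(seq_len(w), ci)
      total <- h * w
      order25 <- sample.int(25L)
      fill_share <- max(min(phi_target * 0.85, 0.68), 0.02)

      cell_span <- function(cell) {
        list(rows = cell_rows[[(cell - 1L) %/% 5L + 1L]],
             cols = cell_cols[[(cell - 1L) %% 5L + 1L]])
      }

      fill_cell <- function(sky, rows, cols, stop_share, small = FALSE) {
        n_cell <- length(rows) * length(cols)
        span <- min(length(rows), length(cols))
        for (it in seq_len(4000L)) {
          share <- sum(sky[rows, cols]) / n_cell
          if (share <= stop_share) break
          ax <- if (small) stats::runif(2, 0.02, 0.05) * span
                else stats::runif(2, 0.10, 0.30) * span
          sky <- paint_ellipse(sky, stats::runif(1, min(rows), max(rows)),
                               stats::runif(1, min(cols), max(cols)),
                               ax[1], ax[2], stats::runif(1, 0, pi),
                               rows, cols, value = FALSE)
        }
        sky
      }

      fc_now <- 0
      cursor <- 1L
      filled_cells <- integer(0)
      while (cursor <= 25L) {
        cell <- order25[cursor]
        cs <- cell_span(cell)
        rows <- cs$rows; cols <- cs$cols
        cell_frac <- length(rows) * length(cols) / total
        delta <- fc_target - fc_now
        if (delta <= 1e-9) break
        remaining <- 25L - cursor + 1L
        partial_capacity <- remaining * 0.23 * cell_frac
        if (delta >= cell_frac || (delta >= cell_frac / 2 &&
                                   partial_capacity < delta)) {
          sky <- fill_cell(sky, rows, cols, fill_share)
          fc_now <- fc_now + cell_frac
          filled_cells <- c(filled_cells, cell)
        } else if (partial_capacity >= delta) {
          # spread the residual cover over edge cells that stay large-gap
          slice <- min(delta, 0.225 * cell_frac)
          stop_share <- max(1 - slice / cell_frac, 0.765)
          before <- sum(sky[rows, cols])
          sky <- fill_cell(sky, rows, cols, stop_share, small = TRUE)
          fc_now <- fc_now + (before - sum(sky[rows, cols])) / total
        } else break
        cursor <- cursor + 1L
      }

      # porosity tuning: punch holes inside filled (non-large) cells.
      # phi = sky_in_crown_cells / (total - sky_in_large_cells), so with
      # the large cells fixed the pixel deficit is known in closed form.
      if (length(filled_cells) > 0L) {
        cell_n <- vapply(seq_len(25L), function(cl) {
          cs <- cell_span(cl); length(cs$rows) * length(cs$cols)
        }, numeric(1))
        cell_sky <- vapply(seq_len(25L), function(cl) {
          cs <- cell_span(cl); sum(sky[cs$rows, cs$cols])
        }, numeric(1))
        large <- cell_sky / cell_n >= 0.75
        s_large <- sum(cell_sky[large])
        s_nl <- sum(cell_sky[!large])
        needed <- phi_target * (total - s_large) - s_nl
        share_cap <- min(0.70, phi_target + 0.2)
        it <- 0L
        while (needed > 0 && it < 20000L) {
          it <- it + 1L
          cell <- filled_cells[sample.int(length(filled_cells), 1L)]
          if (cell_sky[cell] / cell_n[cell] >= share_cap) next
          cs <- cell_span(cell)
          before <- cell_sky[cell]
          r <- stats::runif(1, 2, 6)
          sky <- paint_ellipse(sky, stats::runif(1, min(cs$rows), max(cs$rows)),
                               stats::runif(1, min(cs$cols), max(cs$cols)),
                               r, r, 0, cs$rows, cs$cols, value = TRUE)
          cell_sky[cell] <- sum(sky[cs$rows, cs$cols])
          needed <- needed - (cell_sky[cell] - before)
        }
      }
    }

    cm <- cover_metrics(grid_gap_counts(sky))
    frame <- render_scene(sky)
    list(frame = frame, sky = sky,
         truth = list(fc_target = fc_target, phi_target = phi_target,
                      ff = cm$ff, fc = cm$fc, phi = cm$phi,
                      lai = cm$lai, seed = seed))
  })
}

# Render a sky mask as an 8-bit RGB frame with Gaussian colour noise.
render_scene <- function(sky, noise_sd = 10) {
  h <- nrow(sky); w <- ncol(sky)
  sky_col <- c(135, 160, 220)
  can_col <- c(55, 95, 60)
  frame <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    base <- ifelse(sky, sky_col[ch], can_col[ch])
    frame[, , ch] <- round(pmin(pmax(base + stats::rnorm(h * w, 0, noise_sd),
                                     0), 255))
  }
  frame
}

#' Generate a radiometric thermal frame over a known canopy mask
#'
#' Sky pixels sit at `t_sky` (plus 0.5 C of noise, as a real radiometric
#' sky does); canopy pixels are Gaussian around `t_canopy_mean`.
#'
#' @param canopy_mask Logical matrix, `TRUE` = canopy.
#' @param t_sky Sky radiometric temperature, C (default -30).
#' @param t_canopy_mean,t_canopy_sd Canopy temperature distribution
#'   (defaults 20 and 2 C).
#' @param seed Integer seed.
#' @return A `thermal_frame` with attribute `truth` (the arguments).
#' @export
gen_thermal_scene <- function(canopy_mask, t_sky = -30, t_canopy_mean = 20,
                              t_canopy_sd = 2, seed = 1L) {
  stopifnot(is.logical(canopy_mask), is.matrix(canopy_mask))
  with_seed(seed, {
    temps <- matrix(t_sky + stats::rnorm(length(canopy_mask), 0, 0.5),
                    nrow(canopy_mask), ncol(canopy_mask))
    n_can <- sum(canopy_mask)
    if (n_can > 0)
      temps[canopy_mask] <- stats::rnorm(n_can, t_canopy_mean, t_canopy_sd)
    fr <- thermal_frame(temps)
    attr(fr, "truth") <- list(t_sky = t_sky, t_canopy_mean = t_canopy_mean,
                              t_canopy_sd = t_canopy_sd, seed = seed)
    fr
  })
}

#' Generate a straight street transect with known tree pass times
#'
#' Collinear tree anchors at fixed spacing along a north-south street; the
#' vehicle track starts `lead_m` before the first tree and passes every
#' anchor at constant speed. Ground truth records when the vehicle is
#' abeam of each tree.
#'
#' @param n_trees Number of trees (>= 1).
#' @param spacing_m Anchor spacing in metres (default 30).
#' @param speed_mps Vehicle speed (default 5.6 m/s, a 12-15 min transect).
#' @param rate_hz Raw GPS logging rate (default 1).
#' @param jitter_m GPS noise standard deviation in metres (default 0).
#' @param lead_m Track lead-in/out distance before the first and after the
#'   last tree (default 30).
#' @param lat0,lon0 Origin of the transect (default: Melbourne).
#' @param t0 Start time (POSIXct; default 2021-04-19 15:00:00 UTC).
#' @param seed Integer seed (used only when `jitter_m > 0`).
#' @return List with `track` (a `geo_track`), `anchors` (tree anchor
#'   `data.frame`), and `truth`: `data.frame` of `tree_id`, `pass_time_s`
#'   (seconds from track start), `speed_mps`.
#' @export
gen_transect <- function(n_trees, spacing_m = 30, speed_mps = 5.6,
                         rate_hz = 1, jitter_m = 0, lead_m = 30,
                         lat0 = -37.790, lon0 = 144.958,
                         t0 = as.POSIXct("2021-04-19 15:00:00", tz = "UTC"),
                         seed = 1L) {
  stopifnot(n_trees >= 1L)
  m_per_deg <- EARTH_RADIUS_M * pi / 180
  tree_y <- (seq_len(n_trees) - 1L) * spacing_m
  anchors <- data.frame(tree_id = sprintf("T%02d", seq_len(n_trees)),
                        latitude = lat0 + tree_y / m_per_deg,
                        longitude = lon0)
  path_len <- lead_m + tree_y[n_trees] + lead_m
  tt <- seq(0, path_len / speed_mps, by = 1 / rate_hz)
  y <- -lead_m + speed_mps * tt
  lat <- lat0 + y / m_per_deg
  lon <- rep(lon0, length(tt))
  if (jitter_m > 0) {
    jit <- with_seed(seed, {
      list(lat = stats::rnorm(length(tt), 0, jitter_m) / m_per_deg,
           lon = stats::rnorm(length(tt), 0, jitter_m) /
             (m_per_deg * cos(lat0 * pi / 180)))
    })
    lat <- lat + jit$lat
    lon <- lon + jit$lon
  }
  track <- geo_track(timestamp = t0 + tt, latitude = lat, longitude = lon,
                     altitude = 35)
  truth <- data.frame(tree_id = anchors$tree_id,
                      pass_time_s = (lead_m + tree_y) / speed_mps,
                      speed_mps = speed_mps)
  list(track = track, anchors = anchors, truth = truth)
}

#' Generate a linked gas/physiology dataset with known structure
#'
#' Draws a latent per-tree state (LAI in `[0.3, 4.8]`, water-stress index
#' in `[0.45, 0.9]`), derives the remaining physiology through the thermal
#' relations (fixed references `t_wet` 15 C / `t_dry` 35 C give canopy
#' temperature, Ig and CTD consistent with each other), and maps the
#' latent state through seeded smooth monotone response curves
#' `v = 5 sigmoid(a + b lai/4.8 + c twsi)` into sensor voltages, with
#' Gaussian voltage noise. Sensor responses rise with LAI and stress
#' (MG811 falls with LAI), mirroring the field correlation structure.
#'
#' @param n Number of trees/rows (>= 50).
#' @param noise_sd Voltage noise standard deviation in volts.
#' @param seed Integer seed.
#' @return List with `data` (a per-tree `data.frame` with the nine gas
#'   channels, `temp_C`, `rh_pct`, `twsi`, `ig`, `ctd`, `lai`) and
#'   `truth` (response coefficients, `noise_sd`, `n`, `seed`).
#' @export
gen_linked_dataset <- function(n, noise_sd = 0.05, seed = 1L) {
  stopifnot(n >= 50L)
  with_seed(seed, {
    lai <- stats::runif(n, 0.3, 4.8)
    twsi <- stats::runif(n, 0.45, 0.9)
    t_wet <- 15; t_dry <- 35
    t_canopy <- t_wet + twsi * (t_dry - t_wet)
    ig <- pmin((t_dry - t_canopy) / (t_canopy - t_wet), 10)
    ctd <- -10 + 16 * twsi - 0.5 * lai
    t_average <- t_canopy - ctd
    humidity <- 85 - 30 * twsi

    chans <- ENOSE_CHANNELS
    a <- stats::runif(length(chans), -2.0, -0.8)
    b <- stats::runif(length(chans), 0.6, 1.8)
    cc <- stats::runif(length(chans), 0.4, 1.6)
    b[chans == "MG811"] <- -stats::runif(1, 0.6, 1.8)
    names(a) <- names(b) <- names(cc) <- chans

    volts <- sapply(chans, function(ch)
      5 * sigmoid(a[[ch]] + b[[ch]] * lai / 4.8 + cc[[ch]] * twsi))
    if (noise_sd > 0)
      volts <- volts + matrix(stats::rnorm(length(volts), 0, noise_sd),
                              nrow(volts), ncol(volts))
    volts <- pmin(pmax(volts, 0), 5)

    data <- data.frame(tree_id = sprintf("S%04d", seq_len(n)), volts,
                       temp_C = t_average, rh_pct = humidity,
                       twsi = twsi, ig = ig, ctd = ctd, lai = lai)
    list(data = data,
         truth = list(a = a, b = b, c = cc, t_wet = t_wet, t_dry = t_dry,
                      noise_sd = noise_sd, n = n, seed = seed))
  })
}

#' Write a full synthetic campaign to disk
#'
#' Materialises one transect campaign in the on-disk formats the pipeline
#' readers consume: per-tree RGB frames (PNG), thermal frames (CSV
#' temperature matrices), an SRT GPS sidecar for the camera, a 1 Hz E-nose
#' CSV log, a tree-anchor CSV, and a ground-truth CSV of the generated
#' per-tree values.
#'
#' @param dir Output directory (created).
#' @param n_trees Number of trees (default 6).
#' @param image_px Side length of the square frames (default 160).
#' @param seed Integer seed.
#' @return Invisibly, a list of the paths written plus the truth table.
#' @export
simulate_campaign <- function(dir, n_trees = 6L, image_px = 160L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rgb_dir <- file.path(dir, "rgb"); dir.create(rgb_dir, showWarnings = FALSE)
  th_dir <- file.path(dir, "thermal"); dir.create(th_dir, showWarnings = FALSE)

  tr <- gen_transect(n_trees, seed = seed)
  t0 <- tr$track$timestamp[1]
  linked <- gen_linked_dataset(max(n_trees, 50L), noise_sd = 0.02,
                               seed = seed + 1L)
  per_tree_truth <- linked$data[seq_len(n_trees), , drop = FALSE]
  per_tree_truth$tree_id <- tr$anchors$tree_id

  # one RGB + one thermal frame per tree, timestamped at the pass moment
  frame_times <- t0 + tr$truth$pass_time_s
  scene_truths <- vector("list", n_trees)
  for (i in seq_len(n_trees)) {
    fc_i <- min(max(per_tree_truth$lai[i] / 6, 0.25), 0.9)
    scene <- gen_canopy_scene(fc_i, 0.3, image_px, image_px,
                              seed = seed + 10L + i)
    write_rgb_frame(scene$frame,
                    file.path(rgb_dir, sprintf("frame_%03d.png", i)))
    th <- gen_thermal_scene(!scene$sky, t_canopy_mean = 15 + 10 *
                              per_tree_truth$twsi[i], t_canopy_sd = 1,
                            seed = seed + 20L + i)
    utils::write.table(round(th$temperatures, 3),
                       file.path(th_dir, sprintf("frame_%03d.csv", i)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
    scene_truths[[i]] <- scene$truth
  }
  frame_track <- geo_track(timestamp = frame_times,
                           latitude = tr$anchors$latitude,
                           longitude = tr$anchors$longitude, altitude = 35)
  write_srt_track(frame_track, file.path(dir, "frames.srt"))
  write_srt_track(tr$track, file.path(dir, "track.srt"))
  utils::write.csv(tr$anchors, file.path(dir, "anchors.csv"),
                   row.names = FALSE, quote = FALSE)

  # 1 Hz E-nose log: per-tree gas values held while inside each geofence,
  # transect-mean values elsewhere
  ts <- tr$track$timestamp
  base <- colMeans(per_tree_truth[ENOSE_CHANNELS])
  log <- data.frame(timestamp = ts, lat = tr$track$latitude,
                    lon = tr$track$longitude, alt = tr$track$altitude)
  for (ch in ENOSE_CHANNELS) log[[ch]] <- rep(base[[ch]], length(ts))
  log$temp_C <- mean(per_tree_truth$temp_C)
  log$rh_pct <- mean(per_tree_truth$rh_pct)
  rel <- as.numeric(ts - t0, units = "secs")
  for (i in seq_len(n_trees)) {
    near <- abs(rel - tr$truth$pass_time_s[i]) <= 15 / 5.6
    for (ch in ENOSE_CHANNELS) log[[ch]][near] <- per_tree_truth[[ch]][i]
    log$temp_C[near] <- per_tree_truth$temp_C[i]
    log$rh_pct[near] <- per_tree_truth$rh_pct[i]
  }
  write_enose_log(log, file.path(dir, "enose.csv"))

  truth <- per_tree_truth
  truth$lai_scene <- vapply(scene_truths, function(s) s$lai, numeric(1))
  truth$fc_scene <- vapply(scene_truths, function(s) s$fc, numeric(1))
  truth$phi_scene <- vapply(scene_truths, function(s) s$phi, numeric(1))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)

  invisible(list(dir = dir, anchors = file.path(dir, "anchors.csv"),
                 rgb = rgb_dir, thermal = th_dir,
                 track = file.path(dir, "track.srt"),
                 frames_srt = file.path(dir, "frames.srt"),
                 enose = file.path(dir, "enose.csv"),
                 truth = truth))
}
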