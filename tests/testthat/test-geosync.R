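t0 <- as.POSIXct("2021-04-19 15:00:00", tz = "UTC")

test_that("track densification interpolates linearly on an inclusive grid", {
  tr <- geo_track(t0 + c(0, 1), latitude = c(0, 0.0010), longitude = c(10, 10))
  d <- densify_track(tr, 10)
  expect_equal(nrow(d), 11)                       # inclusive endpoints
  expect_equal(d$latitude[6], 0.0005)             # t = 0.5 s midpoint
  expect_equal(d$latitude[1], 0)
  expect_equal(d$latitude[11], 0.0010)

  # idempotence on an already-dense track
  d2 <- densify_track(d, 10)
  expect_equal(d2$latitude, d$latitude, tolerance = 1e-12)
  expect_equal(as.numeric(d2$timestamp), as.numeric(d$timestamp))

  expect_error(geo_track(t0 + c(1, 0), latitude = c(0, 0), longitude = c(0, 0)),
               "strictly increasing")
})

test_that("geofence radii follow the capped half-spacing rule", {
  m_per_deg <- 6371008.8 * pi / 180
  mk <- function(spacing) data.frame(
    tree_id = c("a", "b", "c"),
    latitude = c(0, spacing, 2 * spacing) / m_per_deg,
    longitude = 0)
  expect_equal(build_geofences(mk(40))$radius_m, rep(15, 3), tolerance = 1e-6)
  expect_equal(build_geofences(mk(20))$radius_m, rep(10, 3), tolerance = 1e-6)
  one <- build_geofences(data.frame(tree_id = "a", latitude = 0, longitude = 0))
  expect_equal(one$radius_m, 15)
  dup <- data.frame(tree_id = c("a", "b"), latitude = c(1, 1), longitude = c(2, 2))
  expect_error(build_geofences(dup), "degenerate")
})

test_that("region intervals recover kinematic pass windows", {
  tr <- gen_transect(20, spacing_m = 30, speed_mps = 5.6, seed = 4)
  dense <- densify_track(tr$track, 10)
  fences <- build_geofences(tr$anchors)
  iv <- region_intervals(dense, fences)
  expect_equal(sort(unique(iv$tree_id)), sort(tr$anchors$tree_id))
  for (i in seq_len(20)) {
    r <- iv[iv$tree_id == tr$anchors$tree_id[i], ]
    true_entry <- tr$truth$pass_time_s[i] - fences$radius_m[i] / 5.6
    true_exit <- tr$truth$pass_time_s[i] + fences$radius_m[i] / 5.6
    expect_lt(abs(as.numeric(r$entry_time - t0, units = "secs") - true_entry), 0.1)
    expect_lt(abs(as.numeric(r$exit_time - t0, units = "secs") - true_exit), 0.1)
    # straight pass through a 15 m region at 5.6 m/s lasts ~2r/v
    expect_equal(as.numeric(r$exit_time - r$entry_time, units = "secs"),
                 2 * fences$radius_m[i] / 5.6, tolerance = 0.2)
  }

  # track far away from every region
  far <- geo_track(t0 + 0:9, latitude = 10 + (0:9) * 1e-5, longitude = 20)
  expect_equal(nrow(region_intervals(densify_track(far, 10), fences)), 0)

  # stationary track inside one region spans the whole track
  still <- geo_track(t0 + seq(0, 5, 0.5),
                     latitude = tr$anchors$latitude[1] + seq(0, 5, 0.5) * 1e-9,
                     longitude = tr$anchors$longitude[1])
  ds <- densify_track(still, 10)
  iv2 <- region_intervals(ds, fences)
  one <- iv2[iv2$tree_id == tr$anchors$tree_id[1], ]
  expect_equal(as.numeric(one$entry_time), as.numeric(ds$timestamp[1]))
  expect_equal(as.numeric(one$exit_time), as.numeric(ds$timestamp[nrow(ds)]))
})

test_that("no track sample is assigned to two different trees", {
  tr <- gen_transect(12, spacing_m = 25, seed = 6)
  dense <- densify_track(tr$track, 10)
  fences <- build_geofences(tr$anchors)
  iv <- region_intervals(dense, fences)
  assigned <- integer(nrow(dense))
  for (k in seq_len(nrow(iv))) {
    inside <- dense$timestamp >= iv$entry_time[k] &
      dense$timestamp <= iv$exit_time[k]
    assigned[inside] <- assigned[inside] + 1L
  }
  expect_true(all(assigned <= 1L))
})

test_that("interval aggregation matches a filter-and-average oracle", {
  iv <- data.frame(tree_id = c("a", "b"),
                   entry_time = t0 + c(0, 10),
                   exit_time = t0 + c(5, 15),
                   pass = 1L)
  st <- data.frame(timestamp = t0 + c(1, 2, 3, 11, 12, 20),
                   v = c(1, 2, 3, 10, 20, 99))
  agg <- aggregate_by_interval(st, iv)
  expect_equal(agg$v[agg$tree_id == "a"], 2)
  expect_equal(agg$v[agg$tree_id == "b"], 15)
  expect_equal(agg$n_v, c(3L, 2L))

  # constant stream: every tree mean equals the constant
  stc <- data.frame(timestamp = t0 + 0:20, v = 2.5)
  aggc <- aggregate_by_interval(stc, iv)
  expect_true(all(aggc$v == 2.5))

  # empty window yields NA, not zero
  iv2 <- rbind(iv, data.frame(tree_id = "c", entry_time = t0 + 100,
                              exit_time = t0 + 101, pass = 1L))
  agg2 <- aggregate_by_interval(st, iv2)
  expect_true(is.na(agg2$v[agg2$tree_id == "c"]))
  expect_equal(agg2$n_v[agg2$tree_id == "c"], 0L)

  # random stream against a brute-force oracle; conservation of counts
  set.seed(31)
  st3 <- data.frame(timestamp = t0 + sort(runif(200, 0, 30)), v = rnorm(200))
  agg3 <- aggregate_by_interval(st3, iv)
  for (id in c("a", "b")) {
    r <- iv[iv$tree_id == id, ]
    keep <- st3$timestamp >= r$entry_time & st3$timestamp <= r$exit_time
    expect_equal(agg3$v[agg3$tree_id == id], mean(st3$v[keep]))
  }
  expect_lte(sum(agg3$n_v), nrow(st3))
})

test_that("multi-pass transects pool samples per tree", {
  # out-and-back: two passes through the same region merge into one record
  lat <- c(seq(0, 100, by = 5), seq(100, 0, by = -5)) * 1e-5
  tr <- geo_track(t0 + seq_along(lat) - 1, latitude = lat, longitude = 0)
  anchors <- data.frame(tree_id = "mid", latitude = 50e-5, longitude = 0)
  iv <- region_intervals(densify_track(tr, 10), build_geofences(anchors))
  expect_equal(nrow(iv), 2)
  st <- data.frame(timestamp = tr$timestamp, v = seq_along(lat))
  agg <- aggregate_by_interval(st, iv)
  expect_equal(nrow(agg), 1)
  expect_gt(agg$n_v, 2)
})

test_that("SRT sidecars round-trip GPS tracks", {
  tr <- gen_transect(3, seed = 2)$track
  p <- withr::local_tempfile(fileext = ".srt")
  write_srt_track(tr, p)
  back <- read_srt_track(p)
  expect_equal(back$latitude, tr$latitude, tolerance = 1e-7)
  expect_equal(back$longitude, tr$longitude, tolerance = 1e-7)
  expect_equal(as.numeric(back$timestamp), as.numeric(tr$timestamp),
               tolerance = 1e-3)
})
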