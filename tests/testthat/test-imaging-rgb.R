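test_that("channel histograms match a brute-force per-pixel tally", {
  fr <- uniform_frame(10, 10, c(20, 30, 100))
  h <- channel_histogram(fr, "blue")
  expect_equal(h$counts[101], 100L)
  expect_equal(sum(h$counts), 100L)

  fr2 <- uniform_frame(10, 10, c(0, 0, 50))
  fr2[, 4:10, 3] <- 220  # 30 px at 50, 70 px at 220
  h2 <- channel_histogram(fr2, "blue")
  expect_equal(h2$counts[51], 30L)
  expect_equal(h2$counts[221], 70L)

  set.seed(42)
  fr3 <- array(sample(0:255, 3 * 15 * 17, replace = TRUE), c(15, 17, 3))
  for (ch in c("red", "green", "blue")) {
    idx <- match(ch, c("red", "green", "blue"))
    tally <- integer(256)
    for (v in as.vector(fr3[, , idx])) tally[v + 1L] <- tally[v + 1L] + 1L
    expect_identical(channel_histogram(fr3, ch)$counts, tally)
  }
})

test_that("valley threshold sits between the two histogram peaks", {
  # discretized two-Gaussian mixture, equal mass
  x <- 0:255
  counts <- round(1e4 * (dnorm(x, 80, 10) + dnorm(x, 200, 10)))
  thr <- detect_valley_threshold(hist256(counts))
  expect_gte(thr, 110)
  expect_lte(thr, 170)

  # flat valley between isolated spikes: tie broken to lowest intensity
  counts2 <- integer(256)
  counts2[51] <- 30L; counts2[221] <- 70L
  expect_identical(detect_valley_threshold(hist256(counts2)), 51L)

  # unimodal histogram refuses with a bimodality error
  counts3 <- round(1e4 * dnorm(x, 120, 20))
  expect_error(detect_valley_threshold(hist256(counts3)), "bimodal")
})

test_that("binarization labels sky strictly above the threshold", {
  expect_true(all(binarize_sky_canopy(uniform_frame(5, 5, c(0, 0, 255)), 128)$sky))
  expect_false(any(binarize_sky_canopy(uniform_frame(5, 5, c(0, 0, 0)), 128)$sky))

  set.seed(7)
  fr <- array(sample(0:255, 3 * 20 * 20, replace = TRUE), c(20, 20, 3))
  m <- binarize_sky_canopy(fr, 128)
  oracle <- matrix(FALSE, 20, 20)
  for (i in 1:20) for (j in 1:20) oracle[i, j] <- fr[i, j, 3] > 128
  expect_identical(m$sky, oracle)
  expect_equal(m$threshold_used, 128)
  # pixel conservation: every pixel labelled
  expect_equal(sum(m$sky) + sum(!m$sky), 400)
})

test_that("grid gap counts equal the nested-loop oracle", {
  all_sky <- matrix(TRUE, 100, 100)
  gc <- grid_gap_counts(all_sky)
  expect_equal(gc$gap_pixels_total, 10000)
  expect_equal(gc$large_gap_pixels, 10000)

  gc0 <- grid_gap_counts(matrix(FALSE, 100, 100))
  expect_equal(gc0$gap_pixels_total, 0)
  expect_equal(gc0$large_gap_pixels, 0)

  # one all-sky 20x20 sub-image, rest canopy
  m <- matrix(FALSE, 100, 100)
  m[21:40, 41:60] <- TRUE
  gc1 <- grid_gap_counts(m)
  expect_equal(gc1$gap_pixels_total, 400)
  expect_equal(gc1$large_gap_pixels, 400)

  # random masks, including sizes not divisible by 5
  set.seed(11)
  for (i in 1:20) {
    h <- sample(25:180, 1); w <- sample(25:180, 1)
    sky <- random_sky_mask(h, w, runif(1, 0.1, 0.9))
    got <- grid_gap_counts(sky)
    want <- brute_gap_counts(sky)
    expect_equal(got$total_pixels, want$total)
    expect_equal(got$gap_pixels_total, want$gap)
    expect_equal(got$large_gap_pixels, want$large)
  }

  expect_error(grid_gap_counts(matrix(TRUE, 3, 3)), "smaller than grid")
})

test_that("cover metrics follow the Beer-Lambert and clumping relations", {
  # fc = 0.8, phi = 0.3 (ff = 0.56): direct evaluation of the formulas
  cm <- cover_metrics(make_gap_counts(100, 44, 20))
  expect_equal(cm$ff, 0.56)
  expect_equal(cm$fc, 0.80)
  expect_equal(cm$phi, 0.30, tolerance = 1e-12)
  expect_equal(cm$lai, -0.8 * log(0.3) / 0.5, tolerance = 1e-12)
  expect_equal(cm$omega0, (1 - 0.3) * log(1 - 0.56) / (log(0.3) * 0.56),
               tolerance = 1e-12)
  expect_equal(cm$lai, 1.926, tolerance = 1e-3)
  expect_equal(cm$omega0, 0.852, tolerance = 1e-3)
  expect_equal(cm$laie, 1.642, tolerance = 1e-3)

  # all sky: no canopy at all
  cm0 <- cover_metrics(make_gap_counts(100, 100, 100))
  expect_equal(cm0$lai, 0)
  expect_equal(cm0$laie, 0)

  # ff -> 0 with fc > 0: phi clamps near 1 and LAI collapses toward 0
  cm1 <- cover_metrics(make_gap_counts(1000000, 1000000 - 10, 500000))
  expect_lt(cm1$lai, 0.01)
  expect_equal(cm1$phi, 1 - 1e-4)

  expect_error(cover_metrics(make_gap_counts(0, 0, 0)), "zero total")
})

test_that("cover-metric invariants hold across random gap counts", {
  set.seed(23)
  for (i in 1:50) {
    total <- 40000L
    gap <- sample.int(total, 1)
    large <- sample.int(gap, 1)
    cm <- cover_metrics(make_gap_counts(total, gap, large))
    if (cm$lai > 0) {
      expect_equal(cm$laie / cm$lai, cm$omega0, tolerance = 1e-10)
      # ff = fc (1 - phi) whenever phi was not clamped
      if (cm$phi > 1e-4 && cm$phi < 1 - 1e-4)
        expect_equal(cm$ff, cm$fc * (1 - cm$phi), tolerance = 1e-10)
      if (cm$omega0 <= 1) expect_lte(cm$laie, cm$lai + 1e-12)
    }
  }
})

test_that("LAI decreases strictly in porosity at fixed crown cover", {
  phis <- seq(0.05, 0.9, by = 0.05)
  lais <- vapply(phis, function(p) {
    fc <- 0.7; ff <- fc * (1 - p)
    cover_metrics(make_gap_counts(1e6, round((1 - ff) * 1e6),
                                  round((1 - fc) * 1e6)))$lai
  }, numeric(1))
  expect_true(all(diff(lais) < 0))
})

test_that("frame analysis recovers a synthetic scene and batch mode writes a table", {
  sc <- gen_canopy_scene(0.6, 0.3, 260, 260, seed = 5)
  cm <- analyze_rgb_frame(sc$frame)
  expect_lt(abs(cm$fc - sc$truth$fc), 0.03)
  la <- lai_analytic(sc$truth$fc, sc$truth$phi)
  expect_lt(abs(cm$lai - la) / max(la, 0.1), 0.10)

  d <- withr::local_tempdir()
  write_rgb_frame(sc$frame, file.path(d, "a.png"))
  write_rgb_frame(sc$frame, file.path(d, "b.png"))
  tab <- analyze_rgb_dir(d)
  expect_equal(tab$frame_id, c("a", "b"))
  expect_equal(tab$lai[1], tab$lai[2])
  expect_equal(tab$lai[1], cm$lai, tolerance = 1e-6)
})
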