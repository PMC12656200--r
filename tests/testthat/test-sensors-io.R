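t0 <- as.POSIXct("2021-04-19 08:40:00", tz = "UTC")

make_log <- function(n, seed = 1) {
  set.seed(seed)
  df <- data.frame(timestamp = t0 + seq_len(n) - 1,
                   lat = -37.79 + seq_len(n) * 1e-6, lon = 144.958, alt = 35)
  for (ch in ENOSE_CHANNELS) df[[ch]] <- round(runif(n, 0.2, 4.5), 4)
  df$temp_C <- round(runif(n, 12, 22), 2)
  df$rh_pct <- round(runif(n, 40, 80), 2)
  df
}

test_that("E-nose logs round-trip through CSV", {
  log <- make_log(720)  # a 12-minute campaign at 1 Hz
  p <- withr::local_tempfile(fileext = ".csv")
  write_enose_log(log, p)
  back <- read_enose_log(p)
  expect_equal(nrow(back), 720)
  for (ch in ENOSE_CHANNELS) expect_equal(back[[ch]], log[[ch]])
  expect_equal(as.numeric(back$timestamp), as.numeric(log$timestamp))
  expect_equal(back$temp_C, log$temp_C)
  expect_false(any(back$flagged))
})

test_that("out-of-range voltages are flagged but kept; bad schema rejected", {
  log <- make_log(5)
  log$MQ4[3] <- 9.9
  p <- withr::local_tempfile(fileext = ".csv")
  write_enose_log(log, p)
  expect_message(back <- read_enose_log(p), "flagged")
  expect_equal(nrow(back), 5)
  expect_identical(back$flagged, c(FALSE, FALSE, TRUE, FALSE, FALSE))

  # missing channel column
  txt <- readLines(p)
  txt[1] <- sub("MQ135", "MQxx", txt[1])
  writeLines(txt, p)
  expect_error(read_enose_log(p), "MQ135")

  # unparseable timestamp drops only that row
  write_enose_log(log, p)
  txt <- readLines(p)
  txt[3] <- sub("^[^,]+", "not-a-time", txt[3])
  writeLines(txt, p)
  expect_message(back2 <- read_enose_log(p), "unparseable")
  expect_equal(nrow(back2), 4)
})

test_that("baseline adjustment subtracts the warm-up window mean", {
  log <- make_log(60)
  for (ch in ENOSE_CHANNELS) log[[ch]] <- 1.0
  adj <- baseline_adjust(log, 30)
  for (ch in ENOSE_CHANNELS) expect_true(all(adj[[ch]] == 0))

  # ramp minus its baseline mean
  log2 <- make_log(100)
  log2$MQ3 <- seq(0, 0.99, by = 0.01)
  adj2 <- baseline_adjust(log2, 10)
  b <- mean(seq(0, 0.09, by = 0.01))
  expect_equal(adj2$MQ3, log2$MQ3 - b, tolerance = 1e-12)

  # all-zero baseline is the identity
  log3 <- make_log(20)
  for (ch in ENOSE_CHANNELS) log3[[ch]][1:5] <- 0
  adj3 <- baseline_adjust(log3, 5)
  expect_equal(adj3$MQ8, log3$MQ8)
})

test_that("campaign means are arithmetic and permutation-invariant", {
  log <- make_log(2)
  log$MQ3 <- c(1, 3)
  cs <- campaign_means(log, "M1")
  expect_equal(unname(cs$means[["MQ3"]]), 2)
  expect_equal(cs$n_samples, 2)

  one <- campaign_means(log[1, ], "M2")
  expect_equal(unname(one$means[["MQ3"]]), 1)

  big <- make_log(300, seed = 5)
  a <- campaign_means(big, "M3")
  b <- campaign_means(big[sample(nrow(big)), ], "M3")
  expect_equal(a$means, b$means, tolerance = 1e-12)
  expect_equal(a$stacked_total, sum(a$means))
  # brute-force mean oracle
  expect_equal(unname(a$means[["MQ137"]]), sum(big$MQ137) / 300,
               tolerance = 1e-12)
})

test_that("the April weather fixture parses every cell", {
  w <- read_weather_table(system.file("extdata", "weather_2021-04.csv",
                                      package = "canopysense"))
  expect_equal(nrow(w), 4)
  r19 <- w[w$date == "2021-04-19", ]
  expect_equal(r19$t_min, 12)
  expect_equal(r19$t_max, 20.6)
  expect_equal(r19$rainfall, 0)
  expect_equal(r19$mslp_9am, 1018.4)
  expect_equal(r19$wind_dir, "NW")
  expect_equal(r19$ws_3pm, 15)
  r21 <- w[w$date == "2021-04-21", ]
  expect_equal(r21$rainfall, 10.4)
  expect_equal(r21$wind_speed_max, 19)
  r29 <- w[w$date == "2021-04-29", ]
  expect_equal(r29$ws_9am, 0)          # "Calm" cell
  expect_true(is.na(r29$wind_dir_9am)) # blank direction
  expect_equal(r29$rh_9am, 83)
  expect_true(all(w$t_min <= w$t_max))
})

test_that("weather validation rejects inconsistent rows", {
  p <- withr::local_tempfile(fileext = ".csv")
  w <- readLines(system.file("extdata", "weather_2021-04.csv",
                             package = "canopysense"))
  w[2] <- sub("^2021-04-19,12,20.6", "2021-04-19,25,20.6", w[2])
  writeLines(w, p)
  expect_error(read_weather_table(p), "t_min")
})
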