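test_that("network initialisation is seeded and correctly shaped", {
  m <- init_network(10, 20, 4, seed = 3)
  expect_equal(dim(m$w1), c(20L, 10L))
  expect_equal(length(m$b1), 20L)
  expect_equal(dim(m$w2), c(4L, 20L))
  expect_equal(length(m$b2), 4L)
  expect_true(all(abs(canopysense:::pack_params(m)) <= 0.5))
  expect_identical(m$w1, init_network(10, 20, 4, seed = 3)$w1)
  expect_false(identical(m$w1, init_network(10, 20, 4, seed = 4)$w1))
})

test_that("the forward pass matches independent matrix arithmetic", {
  m <- init_network(3, 5, 2, seed = 1)
  # all-zero weights: outputs are the output biases
  z <- m; z$w1[] <- 0; z$b1[] <- 0; z$w2[] <- 0
  x <- matrix(runif(12), 4, 3)
  p <- ann_forward(z, x)
  expect_equal(p, matrix(z$b2, 4, 2, byrow = TRUE))
  # zero input, zero hidden bias: hidden activations are all 0.5
  z2 <- m; z2$b1[] <- 0
  p2 <- ann_forward(z2, matrix(0, 1, 3))
  expect_equal(as.vector(p2), as.vector(z2$w2 %*% rep(0.5, 5) + z2$b2))
  # independent loop-based oracle
  set.seed(8)
  x <- matrix(runif(15), 5, 3)
  want <- matrix(0, 5, 2)
  for (i in 1:5) {
    h <- numeric(5)
    for (j in 1:5) h[j] <- 1 / (1 + exp(-(sum(m$w1[j, ] * x[i, ]) + m$b1[j])))
    for (k in 1:2) want[i, k] <- sum(m$w2[k, ] * h) + m$b2[k]
  }
  expect_equal(ann_forward(m, x), want, tolerance = 1e-12)
  expect_error(ann_forward(m, matrix(0, 2, 4)), "width")
})

test_that("the Jacobian agrees with central finite differences on a 3-3-2 net", {
  m <- init_network(3, 3, 2, seed = 5)
  set.seed(1)
  x <- matrix(runif(12), 4, 3)
  y <- matrix(runif(8), 4, 2)
  jb <- canopysense:::ann_jacobian(m, x, y)
  th <- canopysense:::pack_params(m)
  eps <- 1e-6
  Jfd <- matrix(0, length(jb$e), length(th))
  for (k in seq_along(th)) {
    tp <- th; tp[k] <- tp[k] + eps
    tm <- th; tm[k] <- tm[k] - eps
    ep <- as.vector(y - ann_forward(canopysense:::unpack_params(m, tp), x))
    em <- as.vector(y - ann_forward(canopysense:::unpack_params(m, tm), x))
    Jfd[, k] <- (ep - em) / (2 * eps)
  }
  expect_lt(max(abs(jb$J - Jfd)) / max(abs(Jfd)), 1e-4)
  # residual vector itself
  expect_equal(jb$e, as.vector(y - ann_forward(m, x)), tolerance = 1e-12)
})

test_that("Levenberg-Marquardt drives a representable target to ~zero error", {
  set.seed(2)
  x <- matrix(runif(200 * 10), 200, 10)
  y <- cbind(0.3 * x[, 1] + 0.1, 0.2 * x[, 2], 0.5 * x[, 3] + 0.2,
             0.1 * x[, 4] + 0.4)
  ds <- split_dataset(structure(list(inputs = x, targets = y),
                                class = "scaled_dataset"), seed = 3)
  m <- train_lm(init_network(10, 20, 4, seed = 1), ds, max_epochs = 200)
  expect_lt(min(m$training_log$mse_train), 1e-5)
  # accepted steps only ever decrease training MSE
  expect_true(all(diff(m$training_log$mse_train) <= 1e-15))
})

test_that("a constant dataset converges to the constant predictor", {
  x <- matrix(0.5, 40, 10)
  y <- matrix(rep(c(0.2, 0.4, 0.6, 0.8), each = 40), 40, 4)
  ds <- split_dataset(structure(list(inputs = x, targets = y),
                                class = "scaled_dataset"), seed = 1)
  m <- train_lm(init_network(seed = 2), ds, max_epochs = 50)
  expect_lt(mean((ann_forward(m, x) - y)^2), 1e-10)
})

test_that("training is bit-deterministic under a fixed seed", {
  g <- gen_linked_dataset(80, noise_sd = 0.02, seed = 6)
  ds <- split_dataset(suppressWarnings(build_scaled_dataset(g$data)), seed = 4)
  m1 <- train_lm(init_network(seed = 11), ds, max_epochs = 15)
  m2 <- train_lm(init_network(seed = 11), ds, max_epochs = 15)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$w1, m2$w1)
})

test_that("evaluation returns MSE and pooled Pearson R", {
  m <- init_network(4, 3, 2, seed = 9)
  set.seed(12)
  x <- matrix(runif(40), 10, 4)
  p <- ann_forward(m, x)
  perfect <- ann_evaluate(m, x, p)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$r, 1)
  flipped <- ann_evaluate(m, x, matrix(mean(p), 10, 2) * 2 - p)
  expect_equal(flipped$r, -1)
  # brute-force formulas on a random case
  y <- p + matrix(rnorm(20, 0, 0.1), 10, 2)
  ev <- ann_evaluate(m, x, y)
  expect_equal(ev$mse, sum((y - p)^2) / 20, tolerance = 1e-12)
  pv <- as.vector(p); yv <- as.vector(y)
  r_brute <- sum((pv - mean(pv)) * (yv - mean(yv))) /
    sqrt(sum((pv - mean(pv))^2) * sum((yv - mean(yv))^2))
  expect_equal(ev$r, r_brute, tolerance = 1e-12)
  expect_error(ann_evaluate(m, x[0, , drop = FALSE], y[0, , drop = FALSE]),
               "no rows")
})

test_that("models round-trip through the JSON weight file", {
  m <- init_network(seed = 21)
  p <- withr::local_tempfile(fileext = ".json")
  save_network(m, p)
  back <- load_network(p)
  expect_equal(back$w1, m$w1, tolerance = 1e-12)
  expect_equal(back$b2, m$b2, tolerance = 1e-12)
  x <- matrix(runif(20 * 10), 20, 10)
  expect_equal(ann_forward(back, x), ann_forward(m, x), tolerance = 1e-12)
})

test_that("held-out R stays high on noiseless linked data", {
  g <- gen_linked_dataset(500, noise_sd = 0, seed = 11)
  ds <- split_dataset(suppressWarnings(build_scaled_dataset(g$data)), seed = 7)
  m <- train_lm(init_network(seed = 7), ds, max_epochs = 60)
  fr <- fit_report(m, ds)
  expect_gte(fr$r[fr$stage == "test"], 0.95)
})
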