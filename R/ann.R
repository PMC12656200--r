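# Feed-forward 10-20-4 regression network: logistic-sigmoid hidden layer,
# linear output layer, Levenberg-Marquardt training with validation-based
# early stopping, and MSE / pooled Pearson-R evaluation.

#' Initialise a feed-forward network
#'
#' Weights and biases are drawn uniformly in `[-0.5, 0.5]` from a seeded
#' generator, so the same seed reproduces the same network bit-for-bit.
#'
#' @param n_in,n_hidden,n_out Layer sizes (defaults 10, 20, 4).
#' @param seed Integer seed.
#' @return Object of class `canopy_ann`: list with `w1` (`n_hidden x n_in`),
#'   `b1`, `w2` (`n_out x n_hidden`), `b2`, `seed`, `training_log`.
#' @export
init_network <- function(n_in = 10L, n_hidden = 20L, n_out = 4L, seed = 1L) {
  stopifnot(n_in >= 1L, n_hidden >= 1L, n_out >= 1L)
  rng <- local_rng(seed)
  draw <- function(n) rng$runif(n, min = -0.5, max = 0.5)
  structure(list(
    w1 = matrix(draw(n_hidden * n_in), n_hidden, n_in),
    b1 = draw(n_hidden),
    w2 = matrix(draw(n_out * n_hidden), n_out, n_hidden),
    b2 = draw(n_out),
    seed = seed,
    training_log = NULL
  ), class = "canopy_ann")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass
#'
#' Computes `y = W2 sigma(W1 x + b1) + b2` with the logistic sigmoid on
#' the hidden layer and identity output.
#'
#' @param model A `canopy_ann`.
#' @param inputs Matrix `n x n_in`.
#' @return Matrix `n x n_out` of predictions.
#' @export
ann_forward <- function(model, inputs) {
  inputs <- as.matrix(inputs)
  if (ncol(inputs) != ncol(model$w1))
    stop("input width ", ncol(inputs), " != network n_in ", ncol(model$w1))
  h <- sigmoid(inputs %*% t(model$w1) +
                 matrix(model$b1, nrow(inputs), length(model$b1), byrow = TRUE))
  h %*% t(model$w2) +
    matrix(model$b2, nrow(inputs), length(model$b2), byrow = TRUE)
}

# Flatten / restore the parameter vector (order: w1, b1, w2, b2).
pack_params <- function(model) {
  c(as.vector(model$w1), model$b1, as.vector(model$w2), model$b2)
}

unpack_params <- function(model, theta) {
  nh <- nrow(model$w1); ni <- ncol(model$w1); no <- nrow(model$w2)
  i <- 0L
  model$w1 <- matrix(theta[i + seq_len(nh * ni)], nh, ni); i <- i + nh * ni
  model$b1 <- theta[i + seq_len(nh)]; i <- i + nh
  model$w2 <- matrix(theta[i + seq_len(no * nh)], no, nh); i <- i + no * nh
  model$b2 <- theta[i + seq_len(no)]
  model
}

# Jacobian of the residuals e = y - yhat with respect to all parameters.
# Residual rows are ordered output-major: for output k, samples 1..n.
# Returns list(J = (n*n_out) x n_par, e = residual vector, mse).
ann_jacobian <- function(model, inputs, targets) {
  n <- nrow(inputs); nh <- nrow(model$w1); ni <- ncol(model$w1)
  no <- nrow(model$w2)
  z <- inputs %*% t(model$w1) +
    matrix(model$b1, n, nh, byrow = TRUE)
  h <- sigmoid(z)                       # n x nh
  yhat <- h %*% t(model$w2) + matrix(model$b2, n, no, byrow = TRUE)
  e <- as.vector(targets - yhat)        # column-major: output-major blocks
  hp <- h * (1 - h)                     # sigma'(z), n x nh
  n_par <- nh * ni + nh + no * nh + no
  J <- matrix(0, n * no, n_par)
  for (k in seq_len(no)) {
    rows <- (k - 1L) * n + seq_len(n)
    # d yhat_k / d W1[j, m] = w2[k, j] * hp[, j] * x[, m]
    g <- hp * matrix(model$w2[k, ], n, nh, byrow = TRUE)  # n x nh
    for (m in seq_len(ni)) {
      cols <- (m - 1L) * nh + seq_len(nh)   # w1 stored column-major
      J[rows, cols] <- -g * inputs[, m]
    }
    J[rows, nh * ni + seq_len(nh)] <- -g                 # b1
    J[rows, nh * ni + nh + (seq_len(nh) - 1L) * no + k] <- -h  # w2 row k
    J[rows, nh * ni + nh + no * nh + k] <- -1            # b2
  }
  list(J = J, e = e, mse = mean(e^2))
}

#' Train the network with Levenberg-Marquardt
#'
#' Each epoch solves the damped normal equations
#' `(J'J + mu I) delta = J'e` over the training rows, accepting the step
#' only when training MSE decreases (`mu` is divided by `mu_factor` on
#' success and multiplied on failure, retrying within the epoch). Training
#' stops at `max_epochs`, when `mu` overflows `mu_max`, or after
#' `val_fail_limit` consecutive epochs of rising validation MSE; the
#' weights with the best validation MSE are returned.
#'
#' @param model A `canopy_ann` from [init_network()].
#' @param dataset A split `scaled_dataset` (see [split_dataset()]); rows
#'   labelled `train` are optimised, `val` drives early stopping.
#' @param mu0 Initial damping (default 1e-3).
#' @param mu_factor Damping multiplier (default 10).
#' @param mu_max Damping overflow cap (default 1e10).
#' @param max_epochs Epoch cap (default 1000).
#' @param val_fail_limit Consecutive validation failures tolerated
#'   (default 6).
#' @param min_grad Stop when the gradient norm falls below this
#'   (default 1e-10).
#' @return The trained `canopy_ann`; `training_log` holds per-epoch
#'   `mse_train`, `mse_val` and `mu`, and `epochs_run` the count.
#' @export
train_lm <- function(model, dataset, mu0 = 1e-3, mu_factor = 10,
                     mu_max = 1e10, max_epochs = 1000L, val_fail_limit = 6L,
                     min_grad = 1e-10) {
  stopifnot(!is.null(dataset$split))
  tr <- dataset$split == "train"
  va <- dataset$split == "val"
  x_tr <- dataset$inputs[tr, , drop = FALSE]
  y_tr <- dataset$targets[tr, , drop = FALSE]
  x_va <- dataset$inputs[va, , drop = FALSE]
  y_va <- dataset$targets[va, , drop = FALSE]
  has_val <- nrow(x_va) > 0L

  theta <- pack_params(model)
  mu <- mu0
  best_theta <- theta
  best_val <- Inf
  val_fails <- 0L
  log_rows <- vector("list", max_epochs)
  epochs <- 0L

  for (epoch in seq_len(max_epochs)) {
    jb <- ann_jacobian(model, x_tr, y_tr)
    g <- crossprod(jb$J, jb$e)          # J'e
    if (sqrt(sum(g^2)) < min_grad) break
    JtJ <- crossprod(jb$J)
    accepted <- FALSE
    while (mu <= mu_max) {
      step <- tryCatch(
        solve(JtJ + mu * diag(nrow(JtJ)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- unpack_params(model, theta + as.vector(step))
        mse_new <- mean((y_tr - ann_forward(cand, x_tr))^2)
        if (mse_new < jb$mse) {
          model <- cand
          theta <- pack_params(model)
          mu <- max(mu / mu_factor, 1e-20)
          accepted <- TRUE
          break
        }
      }
      mu <- mu * mu_factor
    }
    if (!accepted) {
      if (epoch == 1L && mu > mu_max)
        stop("training failure: no descent step found at the damping cap")
      break  # mu overflow: converged as far as LM can go
    }
    epochs <- epoch
    mse_train <- mean((y_tr - ann_forward(model, x_tr))^2)
    mse_val <- if (has_val) mean((y_va - ann_forward(model, x_va))^2) else NA_real_
    log_rows[[epoch]] <- data.frame(epoch = epoch, mse_train = mse_train,
                                    mse_val = mse_val, mu = mu)
    if (has_val) {
      if (mse_val < best_val) {
        best_val <- mse_val
        best_theta <- theta
        val_fails <- 0L
      } else {
        val_fails <- val_fails + 1L
        if (val_fails >= val_fail_limit) break
      }
    } else {
      best_theta <- theta
    }
  }

  model <- unpack_params(model, best_theta)
  model$training_log <- do.call(rbind, log_rows[!vapply(log_rows, is.null,
                                                        logical(1))])
  model$epochs_run <- epochs
  model
}

#' Evaluate predictions: MSE and pooled Pearson R
#'
#' MSE is the mean squared residual over all `n x n_out` entries. R is the
#' Pearson correlation between the flattened predictions and flattened
#' targets — one pooled value across the four outputs, matching how a
#' single R per stage is reported; per-output R values are also returned.
#'
#' @param model A `canopy_ann`.
#' @param inputs,targets Matched matrices.
#' @return List with `mse`, `r`, `r_per_output`, `n`.
#' @export
ann_evaluate <- function(model, inputs, targets) {
  if (nrow(as.matrix(inputs)) == 0L) stop("no rows to evaluate")
  pred <- ann_forward(model, inputs)
  targets <- as.matrix(targets)
  stopifnot(nrow(pred) == nrow(targets))
  list(
    mse = mean((targets - pred)^2),
    r = stats::cor(as.vector(pred), as.vector(targets)),
    r_per_output = vapply(seq_len(ncol(pred)), function(k)
      stats::cor(pred[, k], targets[, k]), numeric(1)),
    n = nrow(pred)
  )
}

#' Fit report over the train/validation/test stages
#'
#' @param model Trained `canopy_ann`.
#' @param dataset Split `scaled_dataset`.
#' @param extra Optional second, untouched dataset (list with
#'   `inputs`/`targets`) evaluated as an additional held-out stage.
#' @return `data.frame` with one row per stage: `stage`, `n`, `mse`, `r`.
#' @export
fit_report <- function(model, dataset, extra = NULL) {
  stage_eval <- function(stage) {
    idx <- dataset$split == stage
    ev <- ann_evaluate(model, dataset$inputs[idx, , drop = FALSE],
                       dataset$targets[idx, , drop = FALSE])
    data.frame(stage = stage, n = ev$n, mse = ev$mse, r = ev$r)
  }
  out <- do.call(rbind, lapply(c("train", "val", "test"), stage_eval))
  if (!is.null(extra)) {
    ev <- ann_evaluate(model, extra$inputs, extra$targets)
    out <- rbind(out, data.frame(stage = "additional_test", n = ev$n,
                                 mse = ev$mse, r = ev$r))
  }
  out
}

#' Save / load a network as JSON
#'
#' The weight file records the architecture, weights, seed and the fixed
#' input/target scaling metadata, so a saved model can score new E-nose
#' data without the training table.
#'
#' @param model A `canopy_ann`.
#' @param path JSON path.
#' @return `path` invisibly (save); a `canopy_ann` (load).
#' @export
save_network <- function(model, path) {
  obj <- list(
    architecture = list(n_in = ncol(model$w1), n_hidden = nrow(model$w1),
                        n_out = nrow(model$w2)),
    w1 = model$w1, b1 = model$b1, w2 = model$w2, b2 = model$b2,
    seed = model$seed,
    input_order = ANN_INPUTS, target_order = ANN_TARGETS,
    scaling = list(voltage_divisor = 5, temperature_divisor = 50,
                   humidity_divisor = 100, lai_divisor = 5,
                   ctd_range = c(-20, 20))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    w1 = matrix(unlist(obj$w1), nrow = obj$architecture[["n_hidden"]]),
    b1 = as.numeric(obj$b1),
    w2 = matrix(unlist(obj$w2), nrow = obj$architecture[["n_out"]]),
    b2 = as.numeric(obj$b2),
    seed = obj$seed,
    training_log = NULL
  ), class = "canopy_ann")
}

#' Predict physiological indices for new E-nose data
#'
#' Scales raw gas/temperature/humidity readings, runs the network, and
#' returns the predictions in physical units via [unscale_targets()].
#'
#' @param object A trained `canopy_ann`.
#' @param voltages Named matrix/vector of gas channels (see
#'   [scale_inputs()]).
#' @param temperature,humidity Ambient conditions.
#' @param ... Unused.
#' @return `data.frame` with `twsi`, `ig`, `ctd`, `lai`.
#' @export
predict.canopy_ann <- function(object, voltages, temperature, humidity, ...) {
  x <- scale_inputs(voltages, temperature, humidity)
  unscale_targets(ann_forward(object, x))
}

#' @export
print.canopy_ann <- function(x, ...) {
  cat(sprintf("Feed-forward network %d-%d-%d (sigmoid hidden, linear output)\n",
              ncol(x$w1), nrow(x$w1), nrow(x$w2)))
  if (!is.null(x$training_log)) {
    n <- nrow(x$training_log)
    cat(sprintf("  trained %d epoch(s); final train MSE %.3g, val MSE %.3g\n",
                n, x$training_log$mse_train[n], x$training_log$mse_val[n]))
  }
  invisible(x)
}
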