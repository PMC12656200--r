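# Feature scaling of the fused per-tree table into [0, 1] network inputs
# and targets, and the random 70/15/15 split.
#
# The network input order is fixed: MQ3, MQ4, MQ8, MQ135, MQ136, MQ137,
# MQ138, MG811, temperature, humidity (MQ7 is deployed on the array but not
# part of the 10-input vector). Targets: twsi, ig, ctd, lai.

#' Network input channel order (10 inputs)
#' @export
ANN_INPUTS <- c("MQ3", "MQ4", "MQ8", "MQ135", "MQ136", "MQ137", "MQ138",
                "MG811", "temperature", "humidity")

#' Network target order (4 outputs)
#' @export
ANN_TARGETS <- c("twsi", "ig", "ctd", "lai")

clip01 <- function(x, what) {
  out <- pmin(pmax(x, 0), 1)
  n <- sum(out != x, na.rm = TRUE)
  if (n > 0) warning(n, " ", what, " value(s) clipped to [0, 1]")
  out
}

#' Scale raw sensor readings to the network input range
#'
#' Sensor voltages are divided by 5 (the 5 V supply), temperature by 50 and
#' relative humidity by 100, mapping each input to `[0, 1]`; out-of-range
#' results are clipped with a warning.
#'
#' @param voltages Named numeric vector (or matrix with named columns) of
#'   the 8 gas channels in [ANN_INPUTS].
#' @param temperature Ambient temperature, Celsius.
#' @param humidity Relative humidity, percent.
#' @return Numeric matrix `n x 10` in [ANN_INPUTS] order.
#' @export
scale_inputs <- function(voltages, temperature, humidity) {
  if (is.null(dim(voltages))) voltages <- t(as.matrix(voltages))
  chans <- setdiff(ANN_INPUTS, c("temperature", "humidity"))
  miss <- setdiff(chans, colnames(voltages))
  if (length(miss)) stop("missing gas channel(s): ", paste(miss, collapse = ", "))
  x <- cbind(voltages[, chans, drop = FALSE] / 5,
             temperature = temperature / 50,
             humidity = humidity / 100)
  colnames(x) <- ANN_INPUTS
  matrix(clip01(x, "input"), nrow(x), ncol(x), dimnames = dimnames(x))
}

#' Scale physiological targets to the network output range
#'
#' TWSI is already in `[0, 1]`; Ig is clipped to `[0, 1]`; CTD is mapped
#' affinely from `[-20, 20]` Celsius to `[0, 1]` (i.e. `(ctd + 20) / 40`);
#' LAI is divided by 5 (field maxima sit near 4.8). Values outside the
#' stated ranges are clipped with a warning.
#'
#' @param twsi,ig,ctd,lai Numeric vectors of equal length.
#' @return Numeric matrix `n x 4` in [ANN_TARGETS] order.
#' @export
scale_targets <- function(twsi, ig, ctd, lai) {
  y <- cbind(twsi = clip01(twsi, "twsi"),
             ig = clip01(ig, "ig"),
             ctd = clip01((ctd + 20) / 40, "ctd"),
             lai = clip01(lai / 5, "lai"))
  y
}

#' Invert target scaling
#'
#' Exact inverse of [scale_targets()] on the clipped domain.
#'
#' @param y Numeric matrix `n x 4` (or 4-vector) in [ANN_TARGETS] order,
#'   entries in `[0, 1]`.
#' @return `data.frame` with columns `twsi`, `ig`, `ctd`, `lai` in
#'   physical units.
#' @export
unscale_targets <- function(y) {
  if (is.null(dim(y))) y <- t(as.matrix(y))
  data.frame(twsi = y[, 1], ig = y[, 2], ctd = y[, 3] * 40 - 20,
             lai = y[, 4] * 5)
}

#' Build a scaled ANN dataset from a fused per-tree table
#'
#' Drops rows with any missing input or target (per-tree means are already
#' aggregates; imputation would manufacture trees), then applies
#' [scale_inputs()] and [scale_targets()].
#'
#' @param per_tree `data.frame` with the gas channels in [ANN_INPUTS]
#'   (temperature/humidity may be named `temp_C`/`rh_pct`), and the targets
#'   `twsi`, `ig`, `ctd`, `lai`. A `tree_id` column is carried through.
#' @return Object of class `scaled_dataset`: list with `inputs` (n x 10),
#'   `targets` (n x 4), `ids`.
#' @export
build_scaled_dataset <- function(per_tree) {
  df <- as.data.frame(per_tree)
  if (!"temperature" %in% names(df) && "temp_C" %in% names(df))
    df$temperature <- df$temp_C
  if (!"humidity" %in% names(df) && "rh_pct" %in% names(df))
    df$humidity <- df$rh_pct
  need <- c(ANN_INPUTS, ANN_TARGETS)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("fused table missing column(s): ",
                         paste(miss, collapse = ", "))
  keep <- stats::complete.cases(df[need])
  if (sum(keep) < nrow(df))
    message("dropping ", nrow(df) - sum(keep), " row(s) with missing values")
  df <- df[keep, , drop = FALSE]
  gas <- as.matrix(df[setdiff(ANN_INPUTS, c("temperature", "humidity"))])
  structure(list(
    inputs = scale_inputs(gas, df$temperature, df$humidity),
    targets = scale_targets(df$twsi, df$ig, df$ctd, df$lai),
    ids = if ("tree_id" %in% names(df)) as.character(df$tree_id)
          else as.character(seq_len(nrow(df)))
  ), class = "scaled_dataset")
}

#' Random 70/15/15 train/validation/test split
#'
#' Permutes rows uniformly at random with a fixed seed, then labels the
#' first 70% train, the next 15% validation and the rest test (sizes
#' rounded to the nearest row; with n = 101 this gives 71/15/15).
#'
#' @param dataset A `scaled_dataset` (or list with `inputs`/`targets`
#'   matrices), n >= 10.
#' @param seed Integer seed for the permutation.
#' @return The dataset with added `split` (factor train/val/test per row)
#'   and `seed`.
#' @export
split_dataset <- function(dataset, seed = 1L) {
  n <- nrow(dataset$inputs)
  if (n < 10L) stop("need at least 10 rows to split")
  n_train <- round(0.70 * n)
  n_val <- round(0.15 * n)
  n_test <- n - n_train - n_val
  rng <- local_rng(seed)
  perm <- rng$sample(n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  dataset$split <- factor(split, levels = c("train", "val", "test"))
  dataset$seed <- seed
  dataset
}

#' @export
print.scaled_dataset <- function(x, ...) {
  cat("Scaled ANN dataset:", nrow(x$inputs), "rows x",
      ncol(x$inputs), "inputs /", ncol(x$targets), "targets\n")
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

# Seed-local RNG: draws do not disturb (or depend on) the global .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    sample = with_state(function(n, ...) sample.int(n, ...))
  )
}
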