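# Upward-facing canopy photography: blue-histogram thresholding, 5x5 grid
# gap analysis, and Beer-Lambert cover metrics (LAI, LAIe, clumping index).

#' Per-channel intensity histogram of an 8-bit RGB frame
#'
#' Tallies pixel intensities of one colour channel into 256 bins (0--255).
#' Upward canopy photographs are bimodal in the blue channel: a dark canopy
#' peak and a bright sky peak, separated by the valley used for binarization.
#'
#' @param frame Numeric array `h x w x 3` with values in `[0, 255]`
#'   (8-bit intensities), as returned by [read_rgb_frame()].
#' @param channel One of `"red"`, `"green"`, `"blue"`.
#' @return Object of class `histogram256`: list with `counts` (integer
#'   vector of length 256, bin i holds intensity i-1) and `channel`.
#' @seealso [detect_valley_threshold()], [binarize_sky_canopy()]
#' @export
channel_histogram <- function(frame, channel = c("blue", "red", "green")) {
  channel <- match.arg(channel)
  frame <- as_rgb_array(frame)
  idx <- switch(channel, red = 1L, green = 2L, blue = 3L)
  v <- as.integer(round(frame[, , idx]))
  counts <- tabulate(v + 1L, nbins = 256L)
  structure(list(counts = counts, channel = channel),
            class = "histogram256")
}

#' Automatic valley threshold between the sky and canopy histogram peaks
#'
#' Smooths the histogram with a centred moving average, locates the two
#' tallest local maxima at least `min_peak_separation` bins apart, and
#' returns the intensity of the minimum smoothed count strictly between
#' them. This automates the manual pick of the lowest point between the two
#' blue-channel peaks; a manual threshold can always be passed straight to
#' [binarize_sky_canopy()] instead.
#'
#' Ties in the valley are broken toward the lowest intensity.
#'
#' @param hist A `histogram256` object.
#' @param smoothing_window Moving-average window in bins (odd; default 11).
#' @param min_peak_separation Minimum distance in bins between the two peaks
#'   (default 30).
#' @param min_peak_height Minimum height of the second peak as a fraction
#'   of the tallest (default 0.05); smaller bumps are noise, not a mode.
#' @return Integer threshold intensity in `[0, 255]`.
#' @export
detect_valley_threshold <- function(hist, smoothing_window = 11L,
                                    min_peak_separation = 30L,
                                    min_peak_height = 0.05) {
  stopifnot(inherits(hist, "histogram256"))
  counts <- as.numeric(hist$counts)
  w <- as.integer(smoothing_window)
  if (w < 1L || w %% 2L == 0L) stop("smoothing_window must be odd and >= 1")
  sm <- stats::filter(counts, rep(1 / w, w), sides = 2)
  sm <- as.numeric(sm)
  # pad ends with shrinking-window means so edge bins stay comparable
  half <- w %/% 2L
  for (i in seq_len(half)) {
    sm[i] <- mean(counts[1:(i + half)])
    j <- 256L - i + 1L
    sm[j] <- mean(counts[(j - half):256L])
  }
  peaks <- local_maxima(sm)
  peaks <- peaks[sm[peaks] >= min_peak_height * max(sm[peaks])]
  peaks <- peaks[order(sm[peaks], decreasing = TRUE)]
  # greedily keep peaks respecting the separation constraint
  kept <- integer(0)
  for (p in peaks) {
    if (all(abs(kept - p) >= min_peak_separation)) kept <- c(kept, p)
    if (length(kept) == 2L) break
  }
  if (length(kept) < 2L) {
    stop("histogram is not bimodal after smoothing; ",
         "supply a manual threshold to binarize_sky_canopy()")
  }
  # refine each smoothed peak to the raw-count maximum inside its window
  kept <- vapply(kept, function(p) {
    win <- max(1L, p - half):min(256L, p + half)
    win[which.max(counts[win])]
  }, integer(1))
  lo <- min(kept); hi <- max(kept)
  if (hi - lo < 2L) stop("histogram peaks are adjacent; supply a manual threshold")
  between <- (lo + 1L):(hi - 1L)
  valley <- between[which.min(counts[between])]  # ties -> lowest intensity
  as.integer(valley - 1L)                        # bin i holds intensity i-1
}

local_maxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    left <- if (i > 1L) x[i - 1L] else -Inf
    right <- if (i < n) x[i + 1L] else -Inf
    x[i] > left && x[i] >= right
  }, logical(1)))
}

#' Binarize a frame into sky and canopy by blue-channel threshold
#'
#' A pixel is labelled sky when its blue intensity is strictly greater than
#' the threshold; everything else is canopy.
#'
#' @param frame Numeric array `h x w x 3`, 8-bit intensities.
#' @param threshold Intensity cut in `[0, 255]`.
#' @return Object of class `sky_canopy_mask`: list with `sky` (logical
#'   matrix, `TRUE` = sky) and `threshold_used`.
#' @export
binarize_sky_canopy <- function(frame, threshold) {
  frame <- as_rgb_array(frame)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 255)
  sky <- frame[, , 3L] > threshold
  structure(list(sky = sky, threshold_used = threshold),
            class = "sky_canopy_mask")
}

#' Gap analysis on a 5x5 sub-image grid
#'
#' Splits the sky/canopy mask into a grid of sub-images (default 5x5) and
#' tallies total pixels, gap (sky) pixels, and large-gap pixels: the sky
#' pixels of sub-images whose sky proportion is at least
#' `large_gap_fraction` (default 75% sky). Image dimensions that do not
#' divide evenly are handled by merging remainder rows/columns into the last
#' grid row/column so every pixel is counted exactly once.
#'
#' @param mask A `sky_canopy_mask`, or a logical matrix (`TRUE` = sky).
#' @param grid_rows,grid_cols Grid dimensions (default 5).
#' @param large_gap_fraction Sky proportion at or above which a sub-image
#'   counts as a large gap (default 0.75).
#' @return Object of class `gap_counts`: list with `total_pixels`,
#'   `gap_pixels_total`, `large_gap_pixels`, `grid_rows`, `grid_cols`,
#'   `large_gap_fraction`.
#' @export
grid_gap_counts <- function(mask, grid_rows = 5L, grid_cols = 5L,
                            large_gap_fraction = 0.75) {
  sky <- if (inherits(mask, "sky_canopy_mask")) mask$sky else mask
  stopifnot(is.logical(sky), is.matrix(sky))
  nr <- nrow(sky); nc <- ncol(sky)
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  if (nr < grid_rows || nc < grid_cols)
    stop("mask (", nr, "x", nc, ") smaller than grid ",
         grid_rows, "x", grid_cols)
  ri <- grid_cell_index(nr, grid_rows)
  ci <- grid_cell_index(nc, grid_cols)
  cell <- (matrix(ri, nr, nc) - 1L) * grid_cols + matrix(ci, nr, nc, byrow = TRUE)
  cell_total <- tabulate(cell, nbins = grid_rows * grid_cols)
  cell_sky <- tabulate(cell[sky], nbins = grid_rows * grid_cols)
  large <- cell_sky / cell_total >= large_gap_fraction
  structure(list(
    total_pixels = nr * nc,
    gap_pixels_total = sum(cell_sky),
    large_gap_pixels = sum(cell_sky[large]),
    grid_rows = grid_rows, grid_cols = grid_cols,
    large_gap_fraction = large_gap_fraction
  ), class = "gap_counts")
}

# Maps pixel positions 1..n to grid cells 1..k; remainder pixels fall into
# the last cell.
grid_cell_index <- function(n, k) {
  base <- n %/% k
  pmin(((seq_len(n) - 1L) %/% base) + 1L, k)
}

#' Cover metrics and leaf area index from gap counts
#'
#' Derives foliage cover `ff` (1 - total gap fraction), crown cover `fc`
#' (1 - large-gap fraction), crown porosity `phi = 1 - ff/fc`, then applies
#' Beer-Lambert light extinction,
#' \deqn{LAI = -f_c \ln(\phi) / k,}
#' the zenith clumping index
#' \deqn{\Omega(0) = (1-\phi)\ln(1-f_f) / (\ln(\phi)\, f_f),}
#' and the effective index \eqn{LAIe = LAI \cdot \Omega(0)}.
#'
#' `phi` is clamped to `[phi_floor, 1 - phi_floor]` so a fully closed crown
#' does not produce an infinite LAI. Degenerate scenes: `fc = 0` (no crown)
#' returns all metrics 0; `ff = 0` with `fc > 0` clamps `phi` near 1 and LAI
#' tends to 0.
#'
#' @param gc A `gap_counts` object.
#' @param k Light-extinction coefficient (default 0.5).
#' @param phi_floor Clamp bound for porosity (default 1e-4).
#' @return Object of class `cover_metrics`: list with `ff`, `fc`, `phi`,
#'   `omega0`, `lai`, `laie`, `k`.
#' @export
cover_metrics <- function(gc, k = 0.5, phi_floor = 1e-4) {
  stopifnot(inherits(gc, "gap_counts"))
  if (gc$total_pixels <= 0) stop("gap counts have zero total pixels")
  ff <- 1 - gc$gap_pixels_total / gc$total_pixels
  fc <- 1 - gc$large_gap_pixels / gc$total_pixels
  if (fc <= 0) {
    out <- list(ff = 0, fc = 0, phi = 0, omega0 = 0, lai = 0, laie = 0, k = k)
    return(structure(out, class = "cover_metrics"))
  }
  phi <- 1 - ff / fc
  phi <- min(max(phi, phi_floor), 1 - phi_floor)
  lai <- -fc * log(phi) / k
  omega0 <- if (ff <= 0) 1 else (1 - phi) * log(1 - ff) / (log(phi) * ff)
  laie <- lai * omega0
  structure(list(ff = ff, fc = fc, phi = phi, omega0 = omega0,
                 lai = lai, laie = laie, k = k),
            class = "cover_metrics")
}

#' Analytic LAI for a known cover/porosity pair
#'
#' Closed-form Beer-Lambert LAI used to check pipeline recovery against
#' scenes with known ground truth.
#'
#' @param fc Crown cover in `[0, 1]`.
#' @param phi Crown porosity in `(0, 1)`.
#' @param k Extinction coefficient (default 0.5).
#' @return LAI value.
#' @export
lai_analytic <- function(fc, phi, k = 0.5) {
  ifelse(fc <= 0, 0, -fc * log(pmin(pmax(phi, 1e-4), 1 - 1e-4)) / k)
}

#' Full RGB cover analysis of one frame
#'
#' Convenience wrapper: blue histogram, valley threshold (unless supplied),
#' binarization, grid gap analysis and cover metrics in one call.
#'
#' @param frame Numeric array `h x w x 3`, 8-bit intensities.
#' @param threshold Optional manual threshold; when `NULL` the valley is
#'   detected automatically.
#' @param grid_rows,grid_cols,large_gap_fraction,k,phi_floor Passed through
#'   to [grid_gap_counts()] and [cover_metrics()].
#' @return A `cover_metrics` object with the extra fields `threshold` and
#'   `gap_counts`.
#' @export
analyze_rgb_frame <- function(frame, threshold = NULL, grid_rows = 5L,
                              grid_cols = 5L, large_gap_fraction = 0.75,
                              k = 0.5, phi_floor = 1e-4) {
  if (is.null(threshold)) {
    threshold <- detect_valley_threshold(channel_histogram(frame, "blue"))
  }
  mask <- binarize_sky_canopy(frame, threshold)
  gc <- grid_gap_counts(mask, grid_rows, grid_cols, large_gap_fraction)
  cm <- cover_metrics(gc, k = k, phi_floor = phi_floor)
  cm$threshold <- threshold
  cm$gap_counts <- gc
  cm
}

#' Batch RGB analysis over a directory of frames
#'
#' Processes every PNG/TIFF frame in a directory (lexicographic order) and
#' returns a per-frame table. Frames whose histogram is not bimodal are
#' reported with `NA` metrics unless a manual threshold is given.
#'
#' @param dir Directory of 8-bit RGB frames (`.png`, `.tif`, `.tiff`).
#' @param threshold Optional manual threshold applied to all frames.
#' @param ... Passed to [analyze_rgb_frame()].
#' @return `data.frame` with columns `frame_id`, `threshold`, `ff`, `fc`,
#'   `phi`, `omega0`, `lai`, `laie`.
#' @export
analyze_rgb_dir <- function(dir, threshold = NULL, ...) {
  files <- list_frame_files(dir, c("png", "tif", "tiff"))
  rows <- lapply(files, function(f) {
    frame <- read_rgb_frame(f)
    cm <- tryCatch(analyze_rgb_frame(frame, threshold = threshold, ...),
                   error = function(e) NULL)
    if (is.null(cm)) {
      data.frame(frame_id = frame_id_of(f), threshold = NA_real_,
                 ff = NA_real_, fc = NA_real_, phi = NA_real_,
                 omega0 = NA_real_, lai = NA_real_, laie = NA_real_)
    } else {
      data.frame(frame_id = frame_id_of(f), threshold = cm$threshold,
                 ff = cm$ff, fc = cm$fc, phi = cm$phi,
                 omega0 = cm$omega0, lai = cm$lai, laie = cm$laie)
    }
  })
  do.call(rbind, rows)
}

#' @export
print.cover_metrics <- function(x, ...) {
  cat("Canopy cover metrics\n")
  cat(sprintf("  ff (foliage cover) : %.4f\n", x$ff))
  cat(sprintf("  fc (crown cover)   : %.4f\n", x$fc))
  cat(sprintf("  phi (porosity)     : %.4f\n", x$phi))
  cat(sprintf("  Omega(0)           : %.4f\n", x$omega0))
  cat(sprintf("  LAI                : %.4f\n", x$lai))
  cat(sprintf("  LAIe               : %.4f\n", x$laie))
  invisible(x)
}

# ---- internal helpers -------------------------------------------------------

as_rgb_array <- function(frame) {
  if (is.matrix(frame)) stop("frame must have 3 colour channels")
  stopifnot(is.array(frame), length(dim(frame)) == 3L, dim(frame)[3] >= 3L)
  if (prod(dim(frame)[1:2]) == 0L) stop("empty frame")
  frame
}

list_frame_files <- function(dir, exts) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  pat <- paste0("\\.(", paste(exts, collapse = "|"), ")$")
  files <- sort(list.files(dir, pattern = pat, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frames matching ", pat, " in ", dir)
  files
}

frame_id_of <- function(path) sub("\\.[^.]+$", "", basename(path))
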