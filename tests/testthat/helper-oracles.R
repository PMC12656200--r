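# Independent brute-force oracles, deliberately written as plain nested
# loops so they share no code path with the implementation.

hist256 <- function(counts, channel = "blue") {
  stopifnot(length(counts) == 256L)
  structure(list(counts = as.integer(counts), channel = channel),
            class = "histogram256")
}

make_gap_counts <- function(total, gap, large, rows = 5L, cols = 5L) {
  structure(list(total_pixels = total, gap_pixels_total = gap,
                 large_gap_pixels = large, grid_rows = rows,
                 grid_cols = cols, large_gap_fraction = 0.75),
            class = "gap_counts")
}

# nested-loop tally of gap pixels over the sub-image grid, remainder
# rows/cols merged into the last sub-image
brute_gap_counts <- function(sky, grid = 5L, lg = 0.75) {
  nr <- nrow(sky); nc <- ncol(sky)
  br <- nr %/% grid; bc <- nc %/% grid
  gap_total <- 0L; large_total <- 0L
  for (i in seq_len(grid)) {
    for (j in seq_len(grid)) {
      r0 <- (i - 1L) * br + 1L
      r1 <- if (i == grid) nr else i * br
      c0 <- (j - 1L) * bc + 1L
      c1 <- if (j == grid) nc else j * bc
      n_sky <- 0L; n_all <- 0L
      for (r in r0:r1) for (cc in c0:c1) {
        n_all <- n_all + 1L
        if (sky[r, cc]) n_sky <- n_sky + 1L
      }
      gap_total <- gap_total + n_sky
      if (n_sky / n_all >= lg) large_total <- large_total + n_sky
    }
  }
  list(total = nr * nc, gap = gap_total, large = large_total)
}

# uniform frame with a given RGB triple
uniform_frame <- function(h, w, rgb) {
  fr <- array(0, c(h, w, 3))
  for (ch in 1:3) fr[, , ch] <- rgb[ch]
  fr
}

random_sky_mask <- function(h, w, p_sky) {
  matrix(stats::runif(h * w) < p_sky, h, w)
}
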