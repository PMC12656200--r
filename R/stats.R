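# PCA with factor loadings on the correlation matrix, and a
# significance-annotated Pearson correlation matrix, for the fused table of
# gas means, vegetation indices and weather variables.

#' Principal component analysis on standardized variables
#'
#' Because the fused table mixes volts, Celsius, hPa and unitless indices,
#' variables are z-scored first (correlation-matrix PCA). Components are
#' ordered by decreasing eigenvalue; the sign of each loading column is
#' fixed so that its largest-magnitude loading is positive, making outputs
#' reproducible across eigen solvers.
#'
#' @param x Numeric matrix or data.frame, observations x variables, no
#'   missing values, >= 2 of each.
#' @param standardize Z-score the columns first (default `TRUE`).
#' @return Object of class `canopy_pca`: list with `loadings`
#'   (variables x components), `explained_pct`, `scores`, `sdev`.
#' @export
canopy_pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("PCA needs at least 2 observations and 2 variables")
  if (any(!is.finite(x))) stop("PCA input contains missing values")
  if (standardize) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0))
      stop("constant column(s): ",
           paste(colnames(x)[sds == 0], collapse = ", "),
           " cannot be standardized")
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = standardize)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(
    loadings = load,
    explained_pct = 100 * ev / sum(ev),
    scores = scores,
    sdev = pc$sdev
  ), class = "canopy_pca")
}

#' @export
print.canopy_pca <- function(x, ...) {
  k <- min(2L, length(x$explained_pct))
  cat("PCA:", nrow(x$loadings), "variables,",
      nrow(x$scores), "observations\n")
  cat(sprintf("  PC%d: %.2f%%\n", seq_len(k), x$explained_pct[seq_len(k)]))
  invisible(x)
}

#' Pearson correlation matrix with significance
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t transform `t = R sqrt((n-2) / (1-R^2))` on `n - 2` degrees of freedom.
#' Pairs with fewer than 3 complete observations are set to `NA`.
#'
#' @param x Numeric matrix or data.frame, observations x variables.
#' @param alpha Significance level recorded in the result (default 0.05).
#' @return Object of class `correlation_matrix`: list with `r`, `p`, `n`
#'   (pairwise counts), `significant` (logical, `p <= alpha`), `alpha`.
#' @export
pearson_matrix <- function(x, alpha = 0.05) {
  x <- as.matrix(x)
  v <- ncol(x)
  r <- p <- matrix(NA_real_, v, v, dimnames = list(colnames(x), colnames(x)))
  n <- matrix(0L, v, v, dimnames = dimnames(r))
  for (i in seq_len(v)) {
    for (j in seq_len(i)) {
      ok <- is.finite(x[, i]) & is.finite(x[, j])
      nij <- sum(ok)
      n[i, j] <- n[j, i] <- nij
      if (nij < 3L) next
      rij <- stats::cor(x[ok, i], x[ok, j])
      r[i, j] <- r[j, i] <- rij
      if (i == j) {
        p[i, j] <- 0
      } else if (is.na(rij)) {
        # zero-variance pair
      } else {
        tt <- rij * sqrt((nij - 2) / max(1 - rij^2, .Machine$double.eps))
        pij <- 2 * stats::pt(-abs(tt), df = nij - 2)
        p[i, j] <- p[j, i] <- pij
      }
    }
  }
  diag(r)[n[cbind(seq_len(v), seq_len(v))] >= 3L] <- 1
  structure(list(r = r, p = p, n = n, significant = p <= alpha,
                 alpha = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", ncol(x$r), " variables, * p <= ",
      x$alpha, ")\n", sep = "")
  out <- matrix("", nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  for (i in seq_len(nrow(x$r))) for (j in seq_len(i)) {
    out[i, j] <- if (is.na(x$r[i, j])) "NA" else
      paste0(formatC(x$r[i, j], digits = digits, format = "f"),
             if (!is.na(x$p[i, j]) && x$p[i, j] <= x$alpha && i != j) "*" else "")
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Export PCA and correlation results as CSV files
#'
#' @param pca A `canopy_pca`.
#' @param corr A `correlation_matrix`.
#' @param out_prefix Path prefix; writes `<prefix>_loadings.csv`,
#'   `<prefix>_explained.csv` and `<prefix>_correlation.csv` (lower
#'   triangle, significant cells starred).
#' @return Character vector of the files written, invisibly.
#' @export
export_stats <- function(pca, corr, out_prefix) {
  f1 <- paste0(out_prefix, "_loadings.csv")
  utils::write.csv(round(pca$loadings, 6), f1)
  f2 <- paste0(out_prefix, "_explained.csv")
  utils::write.csv(data.frame(component = seq_along(pca$explained_pct),
                              explained_pct = pca$explained_pct),
                   f2, row.names = FALSE)
  f3 <- paste0(out_prefix, "_correlation.csv")
  v <- ncol(corr$r)
  tri <- matrix("", v, v, dimnames = dimnames(corr$r))
  for (i in seq_len(v)) for (j in seq_len(i)) {
    tri[i, j] <- if (is.na(corr$r[i, j])) "" else
      paste0(format(round(corr$r[i, j], 3)),
             if (!is.na(corr$p[i, j]) && corr$p[i, j] <= corr$alpha && i != j)
               "*" else "")
  }
  utils::write.csv(tri, f3)
  invisible(c(f1, f2, f3))
}
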