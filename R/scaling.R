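# Shared log-log regression engine and spectrum averaging.

#' Ordinary least squares on a log-log scale series
#'
#' Fits ln(measure) on ln(scale) over an index window of a
#' [scale_series()]. Regression indices are 1-based and inclusive,
#' mirroring "Regression Min"/"Regression Max" conventions.
#'
#' @param series a [scale_series()].
#' @param reg_min,reg_max 1-based inclusive index window into the series;
#'   defaults cover the whole series.
#' @param skip_zero if TRUE, points with non-positive measures are dropped
#'   before fitting; if FALSE (default) such points are an error.
#' @return A `scaling_fit` list: `slope`, `intercept`, `r_squared`,
#'   `reg_min`, `reg_max`, `n_points`.
#' @export
loglog_fit <- function(series, reg_min = 1L, reg_max = length(series$scales),
                       skip_zero = FALSE) {
  m <- length(series$scales)
  reg_min <- as.integer(reg_min); reg_max <- as.integer(reg_max)
  if (reg_min < 1L || reg_max > m || reg_max - reg_min < 1L)
    stop_fk("loglog_fit: invalid regression window [%d, %d] for %d points",
            reg_min, reg_max, m)
  idx <- reg_min:reg_max
  s <- series$scales[idx]
  M <- series$measures[idx]
  bad <- !is.finite(M) | M <= 0
  if (any(bad)) {
    if (!skip_zero)
      stop_fk("loglog_fit: log of non-positive measure at index %d (enable skip_zero to drop)",
              idx[which(bad)[1L]])
    s <- s[!bad]; M <- M[!bad]
  }
  if (length(s) < 2L) stop_fk("loglog_fit: degenerate regression (fewer than 2 usable points)")
  x <- log(s); y <- log(M)
  fit <- stats::lm.fit(cbind(1, x), y)
  slope <- unname(fit$coefficients[2L])
  intercept <- unname(fit$coefficients[1L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = slope, intercept = intercept,
                 r_squared = max(0, min(1, r2)),
                 reg_min = reg_min, reg_max = reg_max, n_points = length(s)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit: slope %.5f, intercept %.5f, R2 %.5f, window [%d, %d]>\n",
              x$slope, x$intercept, x$r_squared, x$reg_min, x$reg_max))
  invisible(x)
}

#' Radially averaged Fourier power spectrum of an image or volume
#'
#' Computes the discrete Fourier power spectrum of a 2D or 3D grid and bins
#' it by integer radial wavenumber k = round(|f|) ("circular average" in
#' 2D, "spherical average" in 3D). The returned series holds, for
#' k = 1..floor(min(side)/2), the mean power in bin k against scale k; the
#' DC bin is excluded. With `window = "hanning"` the grid mean is removed
#' and a separable Hann window applied before the transform, suppressing
#' edge leakage.
#'
#' @param grid a [grey_grid()] (2D or 3D), all sides >= 8.
#' @param window `"none"` or `"hanning"`.
#' @return A [scale_series()] of (k, mean power). Attributes `bin_sum`
#'   (total power per radial bin over the full radius range), `bin_count`
#'   and `dc_power` expose the unaveraged binning for energy bookkeeping.
#' @export
radial_power_average <- function(grid, window = c("none", "hanning")) {
  window <- match.arg(window)
  x <- unclass(grid) * 1.0
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(2L, 3L)))
    stop_fk("radial_power_average: grid must be 2D or 3D")
  if (any(d < 8L)) stop_fk("radial_power_average: all sides must be >= 8")
  if (window == "hanning") {
    x <- x - mean(x)
    for (ax in seq_along(d)) {
      h <- 0.5 * (1 - cos(2 * pi * (seq_len(d[ax]) - 1L) / (d[ax] - 1L)))
      shape <- rep(1L, length(d)); shape[ax] <- d[ax]
      x <- x * array(rep(h, each = prod(d[seq_len(ax - 1L)])), dim = d)
    }
  }
  P <- Mod(stats::fft(x))^2
  # integer radial wavenumber per cell: per-axis frequency index is the
  # distance to the nearest periodic image of DC
  r2 <- array(0, dim = d)
  for (ax in seq_along(d)) {
    f <- pmin(seq_len(d[ax]) - 1L, d[ax] - (seq_len(d[ax]) - 1L))
    fa <- rep(f, each = prod(d[seq_len(ax - 1L)]))
    r2 <- r2 + array(fa, dim = d)^2
  }
  k <- as.integer(round_half_up(sqrt(r2)))
  kmax_all <- max(k)
  bin_count <- tabulate(k + 1L, nbins = kmax_all + 1L)
  bs <- rowsum(as.vector(P), as.vector(k))
  bin_sum <- numeric(kmax_all + 1L)
  bin_sum[as.integer(rownames(bs)) + 1L] <- bs[, 1L]
  kmax <- floor(min(d) / 2)
  ks <- seq_len(kmax)
  M <- bin_sum[ks + 1L] / bin_count[ks + 1L]
  if (!any(M > 1e-12 * max(bin_sum[1L], 1)))
    stop_fk("radial_power_average: flat spectrum (all power at DC)")
  out <- scale_series(ks, M)
  attr(out, "bin_sum") <- bin_sum
  attr(out, "bin_count") <- bin_count
  attr(out, "dc_power") <- bin_sum[1L]
  out
}

#' Dyadic scale list
#'
#' Powers of two 1, 2, 4, ... up to floor(max_extent / 2) — the standard
#' scale ladder for box counting and pyramid estimators.
#'
#' @param max_extent integer >= 2 (typically the smallest grid side).
#' @return Integer vector of scales.
#' @export
dyadic_scales <- function(max_extent) {
  if (max_extent < 2) stop_fk("dyadic_scales: max_extent must be >= 2")
  top <- floor(max_extent / 2)
  as.integer(2^(0:floor(log2(top))))
}
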