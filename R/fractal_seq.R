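# Fractal and scaling estimators for 1D sequences.

#' Higuchi fractal dimension of a sequence
#'
#' The genuine Higuchi algorithm: for each delay k = 1..kmax and each
#' offset m = 1..k, the curve length
#' L_m(k) = \[ sum |x(m+ik) - x(m+(i-1)k)| * (N-1)/(n_m k) \] / k with
#' n_m = floor((N-m)/k); L(k) is the mean over offsets, and the dimension
#' is minus the slope of ln L(k) vs ln k over the regression window.
#' Expected range \[1, 2\] for signal graphs.
#'
#' @param seq numeric vector, length >= 2*kmax.
#' @param kmax maximum delay, >= 2 (default 8).
#' @param reg_min,reg_max 1-based inclusive window into k = 1..kmax
#'   (defaults: the full window).
#' @return A `dimension_result` with the estimate, the scaling fit and the
#'   (k, L(k)) series.
#' @export
higuchi_dim_1d <- function(seq, kmax = 8L, reg_min = 1L, reg_max = kmax) {
  x <- as.numeric(seq)
  N <- length(x)
  kmax <- as.integer(kmax)
  if (kmax < 2L) stop_fk("higuchi_dim_1d: kmax must be >= 2")
  if (N < 2L * kmax) stop_fk("higuchi_dim_1d: need N >= 2*kmax (N = %d)", N)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    d <- abs(x[(1L + k):N] - x[1:(N - k)])   # |x(i+k) - x(i)| for all i
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      n_m <- (N - m) %/% k
      if (n_m < 1L) { Lm[m] <- NA_real_; next }
      idx <- m + (seq_len(n_m) - 1L) * k     # positions of x(m+(i-1)k)
      Lm[m] <- sum(d[idx]) * (N - 1) / (n_m * k) / k
    }
    L[k] <- mean(Lm, na.rm = TRUE)
  }
  series <- scale_series(seq_len(kmax), L)
  fit <- loglog_fit(series, reg_min, reg_max)
  new_dimension_result(-fit$slope, fit, "higuchi_1d",
                       list(kmax = kmax), series)
}

#' Katz fractal dimension
#'
#' With unit abscissa spacing: L is the total Euclidean path length, d the
#' maximum distance from the first point, n = N - 1 steps;
#' D = log10(n) / (log10(n) + log10(d / L)).
#'
#' @param seq numeric vector, length >= 3.
#' @return A `dimension_result`.
#' @export
katz_dim <- function(seq) {
  x <- as.numeric(seq)
  N <- length(x)
  if (N < 3L) stop_fk("katz_dim: too short (need N >= 3)")
  steps <- sqrt(1 + diff(x)^2)
  L <- sum(steps)
  i <- seq_len(N) - 1
  d <- max(sqrt(i^2 + (x - x[1L])^2))
  if (d == 0) stop_fk("katz_dim: zero extent")
  n <- N - 1
  D <- log10(n) / (log10(n) + log10(d / L))
  new_dimension_result(D, NULL, "katz", list())
}

#' Petrosian fractal dimension
#'
#' Counts sign changes of the first difference (N_delta) and evaluates
#' D = log10(N) / (log10(N) + log10(N / (N + 0.4 N_delta))).
#'
#' @param seq numeric vector, length >= 3.
#' @return A `dimension_result`; constant input gives D = 1.
#' @export
petrosian_dim <- function(seq) {
  x <- as.numeric(seq)
  N <- length(x)
  if (N < 3L) stop_fk("petrosian_dim: too short (need N >= 3)")
  dx <- diff(x)
  s <- sign(dx)
  s <- s[s != 0]
  n_delta <- if (length(s) < 2L) 0L else sum(s[-1L] != s[-length(s)])
  D <- log10(N) / (log10(N) + log10(N / (N + 0.4 * n_delta)))
  new_dimension_result(D, NULL, "petrosian", list(n_delta = n_delta))
}

#' Sevcik fractal dimension
#'
#' Min-max normalizes abscissa and ordinate to \[0, 1\], computes the
#' normalized path length L and D = 1 + ln(L) / ln(2 (N - 1)).
#'
#' @param seq numeric vector, length >= 2, non-constant.
#' @return A `dimension_result`.
#' @export
sevcik_dim <- function(seq) {
  x <- as.numeric(seq)
  N <- length(x)
  if (N < 2L) stop_fk("sevcik_dim: too short")
  rng <- max(x) - min(x)
  if (rng == 0) stop_fk("sevcik_dim: zero amplitude range")
  y <- (x - min(x)) / rng
  t <- (seq_len(N) - 1) / (N - 1)
  L <- sum(sqrt(diff(t)^2 + diff(y)^2))
  D <- 1 + log(L) / log(2 * (N - 1))
  new_dimension_result(D, NULL, "sevcik", list())
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred sequence into a profile, partitions it into
#' non-overlapping windows of size s, removes a linear trend per window,
#' and pools the residual RMS into F(s). The scaling exponent alpha is the
#' slope of ln F(s) vs ln s over log-spaced window sizes. alpha = 0.5 for
#' uncorrelated noise; alpha = H for fractional Gaussian noise.
#'
#' @param seq numeric vector.
#' @param win_min,win_max smallest and largest window size (defaults 4 and
#'   N/4).
#' @param n_windows number of log-spaced window sizes, default 20.
#' @return A `dimension_result` with `dimension` = alpha.
#' @export
dfa_alpha <- function(seq, win_min = 4L, win_max = NULL, n_windows = 20L) {
  x <- as.numeric(seq)
  N <- length(x)
  win_max <- as.integer(win_max %||% (N %/% 4L))
  win_min <- as.integer(win_min)
  if (N < 4L * win_min || win_max > N %/% 4L || win_max <= win_min)
    stop_fk("dfa_alpha: invalid window range for N = %d", N)
  sizes <- unique(round_half_up(exp(seq(log(win_min), log(win_max),
                                        length.out = n_windows))))
  Y <- cumsum(x - mean(x))
  Fs <- vapply(sizes, function(s) {
    nw <- N %/% s
    m <- matrix(Y[seq_len(nw * s)], nrow = s)
    t <- seq_len(s)
    X <- cbind(1, t)
    # residuals of per-column linear fits, via the shared hat projection
    coef <- solve(crossprod(X), crossprod(X, m))
    res <- m - X %*% coef
    sqrt(mean(res^2))
  }, 0)
  series <- scale_series(sizes, Fs)
  fit <- loglog_fit(series)
  new_dimension_result(fit$slope, fit, "dfa",
                       list(win_min = win_min, win_max = win_max), series)
}

#' Hurst exponent from the power spectral density
#'
#' Fits the spectral exponent beta (P(f) ~ f^-beta) on a Hann-windowed
#' periodogram over the lowest half of the frequencies (by default), and
#' classifies the signal: beta in (-1, 1) -> fGn with H = (beta + 1)/2;
#' beta in \[1, 3) -> fBm with H = (beta - 1)/2 (the boundary beta = 1 is
#' assigned to fBm). For fBm the companion fractal dimension
#' D = (5 - beta)/2 is reported.
#'
#' @param seq numeric vector, length >= 64.
#' @param reg_min,reg_max 1-based window into the frequency-index series;
#'   defaults to the lowest half.
#' @return A `dimension_result` with `dimension` = H and extras `beta`,
#'   `class` (`"fGn"` or `"fBm"`) and `fractal_dim` (fBm only).
#' @export
hurst_psd <- function(seq, reg_min = 1L, reg_max = NULL) {
  x <- as.numeric(seq)
  N <- length(x)
  if (N < 64L) stop_fk("hurst_psd: need N >= 64")
  h <- 0.5 * (1 - cos(2 * pi * (seq_len(N) - 1) / (N - 1)))
  xw <- (x - mean(x)) * h
  P <- Mod(stats::fft(xw))^2
  nf <- N %/% 2L
  f <- seq_len(nf)
  pw <- P[2:(nf + 1L)]
  if (!any(pw > 1e-12 * max(P[1L], 1))) stop_fk("hurst_psd: flat spectrum")
  reg_max <- as.integer(reg_max %||% max(2L, nf %/% 2L))
  series <- scale_series(f, pw)
  fit <- loglog_fit(series, reg_min, reg_max, skip_zero = TRUE)
  beta <- -fit$slope
  cls <- if (beta < 1) "fGn" else "fBm"
  H <- if (cls == "fGn") (beta + 1) / 2 else (beta - 1) / 2
  extra <- list(beta = beta, class = cls)
  if (cls == "fBm") extra$fractal_dim <- (5 - beta) / 2
  new_dimension_result(H, fit, "hurst_psd", list(), series, extra)
}

#' Apply a statistic over analysis windows of a sequence
#'
#' `range_mode = "entire"` evaluates once; `"subsequent_boxes"` uses
#' non-overlapping windows of `box_length` (the remainder is dropped);
#' `"sliding_box"` slides a window of `box_length` by one sample,
#' giving N - L + 1 windows.
#'
#' @param seq numeric vector.
#' @param statistic function mapping a numeric vector to a single real.
#' @param range_mode `"entire"`, `"subsequent_boxes"` or `"sliding_box"`.
#' @param box_length window length in samples (ignored for `"entire"`).
#' @return Data frame with columns `start` (1-based window start), `end`
#'   and `value`.
#' @export
windowed_apply <- function(seq, statistic,
                           range_mode = c("entire", "subsequent_boxes",
                                          "sliding_box"),
                           box_length = 100L) {
  range_mode <- match.arg(range_mode)
  x <- as.numeric(seq)
  N <- length(x)
  L <- as.integer(box_length)
  if (range_mode == "entire") {
    return(data.frame(start = 1L, end = N, value = as.numeric(statistic(x))))
  }
  if (L > N) stop_fk("windowed_apply: box_length %d exceeds N = %d", L, N)
  starts <- if (range_mode == "subsequent_boxes")
    seq(1L, N - L + 1L, by = L) else seq_len(N - L + 1L)
  vals <- vapply(starts, function(s) as.numeric(statistic(x[s:(s + L - 1L)])), 0)
  data.frame(start = starts, end = starts + L - 1L, value = vals)
}
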