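# Surrogate data and noise injection, uniform over sequences, images and
# volumes. Spectral surrogates work on the n-dimensional Fourier transform
# directly, so Hermitian symmetry (and hence a real-valued result) is
# guaranteed by construction for any shape, odd sizes included.

#' Generate one surrogate of a sequence, image or volume
#'
#' Methods: `"shuffle"` permutes all samples uniformly (value multiset
#' preserved exactly); `"gaussian"` draws iid normal values matched to the
#' data's sample mean and SD (destroys both distribution shape and
#' correlation); `"random_phase"` randomizes Fourier phases under Hermitian
#' symmetry, preserving the power spectrum exactly (DC and Nyquist bins are
#' kept, so the mean is untouched); `"aaft"` is the amplitude-adjusted
#' Fourier transform: rank-remap to a Gaussian, phase randomize, rank-remap
#' back to the original values (value multiset preserved exactly, spectrum
#' approximately).
#'
#' @param data numeric vector or [grey_grid()].
#' @param method `"shuffle"`, `"gaussian"`, `"random_phase"` or `"aaft"`.
#' @param seed integer seed or `NULL`.
#' @return Object of the same type and shape as `data`.
#' @export
make_surrogate <- function(data, method = c("shuffle", "gaussian",
                                            "random_phase", "aaft"),
                           seed = NULL) {
  method <- match.arg(method)
  is_grid <- inherits(data, "grey_grid")
  x <- if (is_grid) unclass(data) * 1.0 else as.numeric(data)
  n <- length(x)
  if (method %in% c("random_phase", "aaft") && n < 4L)
    stop_fk("make_surrogate: need at least 4 samples for spectral methods")
  out <- with_seed(seed, {
    switch(method,
      shuffle = {
        y <- x
        y[] <- x[sample.int(n)]
        y
      },
      gaussian = {
        y <- x
        y[] <- stats::rnorm(n, mean(x), stats::sd(x))
        y
      },
      random_phase = phase_randomize(x),
      aaft = aaft_surrogate(x)
    )
  })
  seed_used <- attr(out, "seed_used")
  if (is_grid) {
    out <- pmin(pmax(out, 0), 255)
    dim(out) <- dim(data)
    out <- grey_grid(out)
  }
  attr(out, "seed_used") <- seed_used
  out
}

# Multiply the Fourier transform by unit-modulus Hermitian phase factors:
# the factors are the normalized transform of white Gaussian noise of the
# same shape, so conjugate symmetry holds for any dimensionality. Bins that
# are their own conjugate (DC, Nyquist combinations) are forced to +1, so
# they are untouched and the mean is preserved exactly.
phase_randomize <- function(x) {
  d <- dim(x) %||% length(x)
  G <- stats::fft(array(stats::rnorm(prod(d)), dim = d))
  mg <- Mod(G)
  U <- G / ifelse(mg == 0, 1, mg)
  U[self_conjugate_bins(d)] <- 1 + 0i
  out <- Re(stats::fft(stats::fft(array(x, dim = d)) * U, inverse = TRUE)) / prod(d)
  if (is.null(dim(x))) out <- as.vector(out) else dim(out) <- dim(x)
  out
}

# Logical array marking bins whose frequency index is 0 or N/2 on every
# axis (their own complex conjugate).
self_conjugate_bins <- function(d) {
  sc <- array(TRUE, dim = d)
  for (ax in seq_along(d)) {
    idx <- seq_len(d[ax]) - 1L
    own <- idx == 0L | (d[ax] %% 2L == 0L & idx == d[ax] %/% 2L)
    oa <- rep(own, each = prod(d[seq_len(ax - 1L)]))
    sc <- sc & array(oa, dim = d)
  }
  sc
}

# Theiler's amplitude-adjusted Fourier transform (single pass).
aaft_surrogate <- function(x) {
  n <- length(x)
  shape <- dim(x)
  rk <- rank(as.vector(x), ties.method = "first")
  g <- sort(stats::rnorm(n))[rk]       # Gaussianized copy with x's rank order
  dim(g) <- shape
  gs <- phase_randomize(g)
  rk2 <- rank(as.vector(gs), ties.method = "first")
  out <- sort(as.vector(x))[rk2]
  dim(out) <- shape
  out
}

#' Add noise to a sequence, image or volume
#'
#' Noise kinds and the meaning of `level`: `"gaussian"` adds N(0, level);
#' `"uniform"` adds U(-level, level); `"rayleigh"` and `"exponential"` add
#' centred draws (the distribution's mean is subtracted) with scale
#' `level`; `"salt_pepper"` sets a fraction `level` of positions to the
#' data minimum or maximum (each with probability level/2; for grids the
#' extremes are 0 and 255); `"shot"` replaces each value v by
#' `level * rpois(v / level)` (photon noise with gain `level`). Grid output
#' is clamped to \[0, 255\]. `level = 0` returns the input unchanged.
#'
#' @param data numeric vector or [grey_grid()].
#' @param kind one of `"shot"`, `"salt_pepper"`, `"uniform"`, `"gaussian"`,
#'   `"rayleigh"`, `"exponential"`.
#' @param level nonnegative noise level (per-kind meaning above).
#' @param seed integer seed or `NULL`.
#' @return Object of the same type and shape as `data`.
#' @export
add_noise <- function(data, kind = c("gaussian", "uniform", "salt_pepper",
                                     "shot", "rayleigh", "exponential"),
                      level, seed = NULL) {
  kind <- match.arg(kind)
  if (level < 0) stop_fk("add_noise: level must be nonnegative")
  is_grid <- inherits(data, "grey_grid")
  x <- if (is_grid) unclass(data) * 1.0 else as.numeric(data)
  n <- length(x)
  if (level == 0) return(data)
  out <- with_seed(seed, {
    y <- x
    y[] <- switch(kind,
      gaussian = x + stats::rnorm(n, 0, level),
      uniform  = x + stats::runif(n, -level, level),
      rayleigh = x + (level * sqrt(-2 * log(stats::runif(n))) -
                        level * sqrt(pi / 2)),
      exponential = x + (stats::rexp(n, rate = 1 / level) - level),
      shot     = level * stats::rpois(n, pmax(x, 0) / level),
      salt_pepper = {
        lo <- if (is_grid) 0 else min(x)
        hi <- if (is_grid) 255 else max(x)
        hit <- stats::runif(n) < level
        salt <- stats::runif(n) < 0.5
        ifelse(hit, ifelse(salt, hi, lo), x)
      })
    y
  })
  seed_used <- attr(out, "seed_used")
  if (is_grid) {
    out <- pmin(pmax(out, 0), 255)
    dim(out) <- dim(data)
    out <- grey_grid(out)
  }
  attr(out, "seed_used") <- seed_used
  out
}

#' Evaluate a statistic on data and on an ensemble of its surrogates
#'
#' Runs `statistic` on the original data and on `count` independent
#' surrogates (child seeds derived deterministically from `seed`), and
#' reports the individual surrogate values together with their mean and
#' sample standard deviation.
#'
#' @param data numeric vector or [grey_grid()].
#' @param statistic function mapping the data type to a single real.
#' @param method surrogate method, see [make_surrogate()].
#' @param count number of surrogates, >= 1.
#' @param seed integer base seed or `NULL`.
#' @return A [surrogate_report()].
#' @export
surrogate_ensemble <- function(data, statistic, method = "shuffle",
                               count = 10L, seed = NULL) {
  count <- as.integer(count)
  if (count < 1L) stop_fk("surrogate_ensemble: count must be >= 1")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  seeds <- derive_seeds(seed, count)
  orig <- statistic(data)
  vals <- vapply(seq_len(count), function(i) {
    s <- make_surrogate(data, method, seed = seeds[i])
    v <- tryCatch(statistic(s), error = function(e)
      stop_fk("surrogate_ensemble: statistic failed on surrogate %d: %s",
              i, conditionMessage(e)))
    as.numeric(v)
  }, 0)
  rep <- surrogate_report(as.numeric(orig), vals)
  rep$method <- method
  rep$seed <- as.integer(seed)
  rep
}
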