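# Synthetic test-data factories with known ground-truth structure.
#
# The fractal kinds share one exponent convention: for embedding dimension
# E and target dimension D in (E, E+1), the Hurst exponent is H = E + 1 - D
# and the power-spectral exponent is beta = 2H + E = 3E + 2 - 2D. The three
# canonical walkthroughs (1D D=1.5, 2D D=2.5, 3D D=3.5) all map to
# H = 0.5 and beta = 2, 3, 4 respectively.

#' Generate synthetic 1D sequences
#'
#' @param kind one of `"constant"`, `"sine"`, `"square"`, `"triangle"`,
#'   `"sawtooth"`, `"gaussian"`, `"uniform"`, `"logistic"`, `"henon"`,
#'   `"cubic"`, `"spence"`, `"fgn_dhm"`, `"fbm_ssm"`, `"wm"`, `"cantor"`.
#' @param n sequence length (for `"cantor"` the length is
#'   `round((1/r)^levels)` and `n` is ignored).
#' @param count number of sequences to generate.
#' @param dim target fractal dimension in (1, 2) for `"wm"` and
#'   `"cantor"` (for cantor, `dim` sets the keep ratio `r = 2^(-1/dim)`
#'   unless `r` is given explicitly).
#' @param hurst Hurst exponent in (0, 1) for `"fgn_dhm"` and `"fbm_ssm"`.
#' @param value constant value (kind `"constant"`), default 1.
#' @param period samples per cycle for the periodic kinds, default 32.
#' @param amplitude amplitude of periodic kinds, default 1.
#' @param mean,sd moments of `"gaussian"` noise (default 0, 1); `"uniform"`
#'   draws from `[mean - sd, mean + sd]`.
#' @param a logistic map parameter (default 4) / cubic map parameter
#'   (default 3).
#' @param r cantor keep ratio in (0, 1/2]; overrides `dim`.
#' @param levels cantor recursion depth, default 5.
#' @param seed integer seed; `NULL` draws one from entropy (recorded in the
#'   `"seed_used"` attribute).
#' @return Named list of `count` numeric vectors.
#' @export
generate_sequence <- function(kind, n = 1024L, count = 1L, dim = 1.5,
                              hurst = 0.5, value = 1, period = 32,
                              amplitude = 1, mean = 0, sd = 1, a = NULL,
                              r = NULL, levels = 5L, seed = NULL) {
  kind <- match.arg(kind, c("constant", "sine", "square", "triangle",
                            "sawtooth", "gaussian", "uniform", "logistic",
                            "henon", "cubic", "spence", "fgn_dhm", "fbm_ssm",
                            "wm", "cantor"))
  n <- as.integer(n)
  if (kind %in% c("wm", "cantor") && !(dim > 1 && dim < 2) && is.null(r))
    stop_fk("generate_sequence: dim must lie in (1, 2) for kind '%s'", kind)
  if (kind %in% c("fgn_dhm", "fbm_ssm") && !(hurst > 0 && hurst < 1))
    stop_fk("generate_sequence: hurst must lie in (0, 1)")
  out <- with_seed(seed, {
    lapply(seq_len(count), function(i) {
      switch(kind,
        constant = rep(value, n),
        sine     = amplitude * sin(2 * pi * (seq_len(n) - 1) / period),
        square   = amplitude * sign(sin(2 * pi * (seq_len(n) - 1) / period + 1e-12)),
        triangle = amplitude * (2 / pi) * asin(sin(2 * pi * (seq_len(n) - 1) / period)),
        sawtooth = amplitude * (2 * (((seq_len(n) - 1) / period) %% 1) - 1),
        gaussian = stats::rnorm(n, mean, sd),
        uniform  = stats::runif(n, mean - sd, mean + sd),
        logistic = iterate_map(n, function(x) (a %||% 4) * x * (1 - x),
                               x0 = stats::runif(1, 0.1, 0.9)),
        henon    = henon_seq(n),
        cubic    = iterate_map(n, function(x) (a %||% 3) * x * (1 - x * x),
                               x0 = stats::runif(1, 0.05, 0.95)),
        spence   = iterate_map(n, function(x) abs(log(x)),
                               x0 = stats::runif(1, 0.2, 0.8)),
        fgn_dhm  = fgn_davies_harte(n, hurst),
        fbm_ssm  = fbm_spectral(n, hurst),
        wm       = weierstrass_mandelbrot(n, dim),
        cantor   = cantor_dust(r %||% 2^(-1 / dim), levels)
      )
    })
  })
  seed_used <- attr(out, "seed_used")
  names(out) <- paste0(kind, "_", seq_len(count))
  attr(out, "seed_used") <- seed_used
  out
}

iterate_map <- function(n, f, x0, transient = 100L) {
  x <- x0
  for (i in seq_len(transient)) x <- f(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- x
    x <- f(x)
  }
  out
}

henon_seq <- function(n, a = 1.4, b = 0.3, transient = 100L) {
  x <- stats::runif(1, -0.1, 0.1); y <- stats::runif(1, -0.1, 0.1)
  out <- numeric(n)
  for (i in seq_len(transient + n)) {
    xn <- 1 - a * x * x + y
    y <- b * x
    x <- xn
    if (i > transient) out[i - transient] <- x
  }
  out
}

# Weierstrass-Mandelbrot function with random phases:
#   x(t) = sum_{n0}^{n1} gamma^(-nH) sin(gamma^n t + phi_n),  H = 2 - D.
# gamma = 1.5; the n-range is chosen so gamma^n spans frequencies from
# below one cycle over the record to beyond one cycle per sample.
weierstrass_mandelbrot <- function(n, dim, gamma = 1.5) {
  H <- 2 - dim
  t <- seq(0, 2 * pi, length.out = n)
  nmax <- ceiling(log(n) / log(gamma))
  ns <- (-nmax):nmax
  phi <- stats::runif(length(ns), 0, 2 * pi)
  x <- numeric(n)
  for (j in seq_along(ns)) {
    x <- x + gamma^(-ns[j] * H) * sin(gamma^ns[j] * t + phi[j])
  }
  x
}

# Stationary fractional Gaussian noise by Davies-Harte circulant embedding
# of the fGn autocovariance rho(k) = 0.5 (|k+1|^2H - 2|k|^2H + |k-1|^2H).
fgn_davies_harte <- function(n, H) {
  k <- 0:n
  rho <- 0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
  circ <- c(rho[1:n], rho[n + 1L], rho[n:2])  # length 2n embedding first row
  ev <- Re(stats::fft(circ))
  if (min(ev) < -1e-8 * max(ev))
    stop_fk("fgn_davies_harte: embedding not nonneg-definite (H = %g, n = %d)", H, n)
  ev[ev < 0] <- 0
  m <- 2L * n
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  w <- stats::fft(sqrt(ev / (2 * m)) * z)
  Re(w)[seq_len(n)] + Im(w)[seq_len(n)]
}

# Spectral synthesis of fractional Brownian motion: shape the spectrum of a
# white Gaussian sequence by amplitude f^(-(2H+1)/2) (random phases arrive
# with the noise transform, Hermitian symmetry is automatic), inverse
# transform, real part.
fbm_spectral <- function(n, H) {
  beta <- 2 * H + 1
  W <- stats::fft(stats::rnorm(n))
  f <- pmin(0:(n - 1), n - (0:(n - 1)))
  amp <- c(0, f[-1L]^(-beta / 2))
  Re(stats::fft(W * amp, inverse = TRUE)) / n
}

# Binary Cantor dust: middle-removal with keep-ratio r per end, rasterized
# on round((1/r)^levels) cells by half-open interval arithmetic.
cantor_dust <- function(r, levels) {
  if (!(r > 0 && r <= 0.5)) stop_fk("cantor_dust: keep ratio r must lie in (0, 1/2]")
  n <- round_half_up((1 / r)^levels)
  iv <- matrix(c(0, 1), nrow = 1)      # [a, b) intervals kept so far
  for (l in seq_len(levels)) {
    a <- iv[, 1L]; b <- iv[, 2L]; w <- (b - a) * r
    iv <- rbind(cbind(a, a + w), cbind(b - w, b))
  }
  x <- numeric(n)
  cell <- (seq_len(n) - 0.5) / n       # cell centres
  for (i in seq_len(nrow(iv))) {
    x[cell >= iv[i, 1L] & cell < iv[i, 2L]] <- 1
  }
  x
}

#' Generate synthetic 2D grey images
#'
#' @param kind one of `"random"`, `"gaussian"`, `"sine_radial"`,
#'   `"sine_horizontal"`, `"sine_vertical"`, `"constant"`, `"surface_fft"`,
#'   `"surface_mpd"`, `"ifs_menger"`, `"ifs_sierpinski"`.
#' @param width,height image size in pixels.
#' @param count number of images.
#' @param dim target fractal dimension in (2, 3) for the fractal surfaces
#'   (spectral exponent beta = 8 - 2 dim; Hurst H = 3 - dim).
#' @param grey_max maximum grey value after min-max scaling, default 255.
#' @param period samples per cycle of the sine kinds, default 32.
#' @param levels recursion depth of `"ifs_menger"`; the carpet is drawn on
#'   the largest 3^L <= min(width, height) grid and centred.
#' @param ifs_points chaos-game iterations for `"ifs_sierpinski"`.
#' @param seed integer seed or `NULL`.
#' @return List of `count` [grey_grid()] objects.
#' @export
generate_image <- function(kind, width = 512L, height = 512L, count = 1L,
                           dim = 2.5, grey_max = 255, period = 32,
                           levels = NULL, ifs_points = 200000L, seed = NULL) {
  kind <- match.arg(kind, c("random", "gaussian", "sine_radial",
                            "sine_horizontal", "sine_vertical", "constant",
                            "surface_fft", "surface_mpd", "ifs_menger",
                            "ifs_sierpinski"))
  if (kind %in% c("surface_fft", "surface_mpd") && !(dim > 2 && dim < 3))
    stop_fk("generate_image: dim must lie in (2, 3) for kind '%s'", kind)
  w <- as.integer(width); h <- as.integer(height)
  out <- with_seed(seed, {
    lapply(seq_len(count), function(i) {
      g <- switch(kind,
        random     = matrix(stats::runif(h * w, 0, grey_max), h, w),
        gaussian   = gaussian_spot(h, w, grey_max),
        sine_radial = sine_image(h, w, period, grey_max, "radial"),
        sine_horizontal = sine_image(h, w, period, grey_max, "horizontal"),
        sine_vertical = sine_image(h, w, period, grey_max, "vertical"),
        constant   = matrix(grey_max, h, w),
        surface_fft = spectral_field(c(h, w), beta = 8 - 2 * dim, grey_max),
        surface_mpd = mpd_surface(h, w, H = 3 - dim, grey_max),
        ifs_menger = menger_mask(c(h, w), levels, grey_max),
        ifs_sierpinski = sierpinski_chaos(h, w, ifs_points, grey_max)
      )
      grey_grid(round_half_up(pmin(pmax(g, 0), 255)))
    })
  })
  out
}

gaussian_spot <- function(h, w, grey_max) {
  y <- (seq_len(h) - (h + 1) / 2) / (h / 4)
  x <- (seq_len(w) - (w + 1) / 2) / (w / 4)
  grey_max * exp(-(outer(y^2, x^2, `+`)) / 2)
}

sine_image <- function(h, w, period, grey_max, orient) {
  y <- seq_len(h) - 1; x <- seq_len(w) - 1
  ph <- switch(orient,
    radial = sqrt(outer((y - (h - 1) / 2)^2, (x - (w - 1) / 2)^2, `+`)),
    horizontal = outer(rep(1, h), x),
    vertical = outer(y, rep(1, w)))
  grey_max * (0.5 + 0.5 * sin(2 * pi * ph / period))
}

# Spectral synthesis of an E-dim fractal field: filter white Gaussian noise
# with amplitude |f|^(-beta/2); inverse transform real part; min-max scale.
spectral_field <- function(d, beta, grey_max) {
  W <- stats::fft(array(stats::rnorm(prod(d)), dim = d))
  r2 <- array(0, dim = d)
  for (ax in seq_along(d)) {
    f <- pmin(seq_len(d[ax]) - 1L, d[ax] - (seq_len(d[ax]) - 1L))
    fa <- rep(f, each = prod(d[seq_len(ax - 1L)]))
    r2 <- r2 + array(fa, dim = d)^2
  }
  amp <- r2^(-beta / 4)                # |f|^(-beta/2)
  amp[1L] <- 0                         # kill DC
  x <- Re(stats::fft(W * amp, inverse = TRUE)) / prod(d)
  grey_max * (x - min(x)) / (max(x) - min(x))
}

# Diamond-square midpoint displacement on a (2^k + 1) lattice, cropped.
mpd_surface <- function(h, w, H, grey_max) {
  k <- ceiling(log2(max(h, w) - 1))
  n <- 2L^k + 1L
  z <- matrix(0, n, n)
  z[c(1, n), c(1, n)] <- stats::rnorm(4)
  sd <- 1
  step <- n - 1L
  while (step > 1L) {
    half <- step %/% 2L
    sd <- sd * 2^(-H)
    # diamond step
    ci <- seq(1L + half, n, by = step)
    for (i in ci) for (j in ci) {
      z[i, j] <- mean(z[c(i - half, i + half), c(j - half, j + half)]) +
        stats::rnorm(1, 0, sd)
    }
    # square step
    for (i in seq(1L, n, by = half)) {
      js <- if (((i - 1L) %/% half) %% 2L == 0L) seq(1L + half, n, by = step)
            else seq(1L, n, by = step)
      for (j in js) {
        nb <- c(if (i > half) z[i - half, j], if (i + half <= n) z[i + half, j],
                if (j > half) z[i, j - half], if (j + half <= n) z[i, j + half])
        z[i, j] <- mean(nb) + stats::rnorm(1, 0, sd)
      }
    }
    step <- half
  }
  z <- z[seq_len(h), seq_len(w)]
  grey_max * (z - min(z)) / (max(z) - min(z))
}

# Menger carpet (2D) or cube (3D) membership mask on a 3^L grid, centred in
# the requested extent.
menger_mask <- function(d, levels, grey_max) {
  E <- length(d)
  L <- levels %||% floor(log(min(d)) / log(3) + 1e-9)
  side <- 3L^L
  if (side > min(d))
    stop_fk("menger_mask: 3^%d exceeds the requested size", L)
  coords <- lapply(seq_len(E), function(ax) seq_len(side) - 1L)
  keep <- array(TRUE, dim = rep(side, E))
  for (l in seq_len(L)) {
    digit <- lapply(coords, function(c) (c %/% 3L^(l - 1L)) %% 3L == 1L)
    mid_count <- array(0L, dim = rep(side, E))
    for (ax in seq_len(E)) {
      da <- rep(digit[[ax]], each = side^(ax - 1L))
      mid_count <- mid_count + array(da, dim = rep(side, E))
    }
    keep <- keep & (mid_count < 2L)    # remove cells centred in >= 2 axes
  }
  full <- array(0, dim = d)
  off <- (d - side) %/% 2L
  idx <- lapply(seq_len(E), function(ax) off[ax] + seq_len(side))
  if (E == 2L) full[idx[[1L]], idx[[2L]]] <- keep * grey_max
  else full[idx[[1L]], idx[[2L]], idx[[3L]]] <- keep * grey_max
  full
}

sierpinski_chaos <- function(h, w, n_points, grey_max) {
  v <- matrix(c(0.5, 0, 0, 1, 1, 1), ncol = 2, byrow = TRUE)  # (x, y) in [0,1]
  pts <- matrix(0, n_points, 2)
  p <- stats::runif(2)
  for (i in seq_len(n_points)) {
    vi <- sample.int(3L, 1L)
    p <- (p + v[vi, ]) / 2
    pts[i, ] <- p
  }
  img <- matrix(0, h, w)
  rows <- pmin(h, pmax(1L, 1L + floor((1 - pts[, 2]) * h)))
  cols <- pmin(w, pmax(1L, 1L + floor(pts[, 1] * w)))
  img[cbind(rows, cols)] <- grey_max
  img
}

#' Generate synthetic 3D grey volumes
#'
#' @param kind one of `"random"`, `"gaussian"`, `"constant"`,
#'   `"volume_fft"`, `"ifs_menger_cube"`.
#' @param width,height,depth volume size in voxels.
#' @param dim target fractal dimension in (3, 4) for `"volume_fft"`
#'   (spectral exponent beta = 11 - 2 dim).
#' @param grey_max maximum grey value, default 255.
#' @param levels recursion depth for `"ifs_menger_cube"`.
#' @param max_voxels guard against accidental huge allocations, default
#'   2^28.
#' @param seed integer seed or `NULL`.
#' @return A [grey_grid()] of rank 3 (rows, cols, slices).
#' @export
generate_volume <- function(kind, width = 128L, height = 128L, depth = 128L,
                            dim = 3.5, grey_max = 255, levels = NULL,
                            max_voxels = 2^28, seed = NULL) {
  kind <- match.arg(kind, c("random", "gaussian", "constant", "volume_fft",
                            "ifs_menger_cube"))
  d <- as.integer(c(height, width, depth))
  if (prod(as.numeric(d)) > max_voxels)
    stop_fk("generate_volume: voxel count %g exceeds max_voxels = %g",
            prod(as.numeric(d)), max_voxels)
  if (kind == "volume_fft" && !(dim > 3 && dim < 4))
    stop_fk("generate_volume: dim must lie in (3, 4) for volume_fft")
  g <- with_seed(seed, {
    switch(kind,
      random   = array(stats::runif(prod(d), 0, grey_max), dim = d),
      gaussian = array(stats::rnorm(prod(d), grey_max / 2, grey_max / 8), dim = d),
      constant = array(grey_max, dim = d),
      volume_fft = spectral_field(d, beta = 11 - 2 * dim, grey_max),
      ifs_menger_cube = menger_mask(d, levels, grey_max)
    )
  })
  grey_grid(round_half_up(pmin(pmax(unclass(g), 0), 255)))
}
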