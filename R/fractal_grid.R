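# Fractal estimators for 2D images and 3D volumes.
#
# Scale windows: regression-based estimators default to the central scaling
# region (the smallest and largest scale are dropped when at least four
# scales exist) to reduce finite-size bias; reg_min/reg_max override.

default_window <- function(m) {
  if (m >= 4L) c(2L, m - 1L) else c(1L, m)
}

#' Box-counting fractal dimension of a binary mask (2D or 3D)
#'
#' Tiles the grid with eps-sided boxes anchored at the origin (partial
#' boxes at the far edges count when they contain foreground), counts
#' occupied boxes N(eps), and returns minus the slope of ln N(eps) vs
#' ln eps. The default scale ladder is dyadic; when the smallest side is
#' an exact power of 3 a triadic ladder is used instead, so that the raster
#' aligns with base-3 self-similar sets (Menger carpet/cube) whose counts
#' are then exact.
#'
#' @param mask a `binary_mask` (or [grey_grid()]/array, binarized at
#'   threshold 0).
#' @param reg_min,reg_max 1-based window into the scale ladder; defaults to
#'   the central scaling region for dyadic ladders and the full ladder for
#'   triadic ones.
#' @param scales optional explicit scale ladder (increasing positive
#'   integers).
#' @return A `dimension_result` with the (eps, N(eps)) series.
#' @export
box_counting_dim <- function(mask, reg_min = NULL, reg_max = NULL,
                             scales = NULL) {
  m <- as_mask(mask)
  if (sum(m) == 0L) stop_fk("box_counting_dim: empty foreground")
  side <- min(dim(m))
  triadic <- is.null(scales) && is_power_of(side, 3L)
  scales <- scales %||%
    (if (triadic) 3L^(0:max(1L, floor(log(side / 2) / log(3) + 1e-9)))
     else dyadic_scales(side))
  counts <- vapply(scales, function(e) sum(tile_reduce(unclass(m), e, "max")), 0)
  series <- scale_series(scales, counts)
  w <- if (triadic) c(1L, length(scales)) else default_window(length(scales))
  fit <- loglog_fit(series, reg_min %||% w[1L], reg_max %||% w[2L])
  new_dimension_result(-fit$slope, fit, "box_counting", list(), series)
}

is_power_of <- function(n, b) {
  if (n < b) return(FALSE)
  abs(b^round(log(n) / log(b)) - n) < 1e-9
}

#' Pyramid fractal dimension (2D)
#'
#' Repeatedly downsamples the mask by 2 with logical-OR pooling; the
#' foreground count per level against the pooling factor 2^level plays the
#' role of the box count.
#'
#' @inheritParams box_counting_dim
#' @return A `dimension_result`.
#' @export
pyramid_dim <- function(mask, reg_min = NULL, reg_max = NULL) {
  m <- as_mask(mask)
  if (grid_rank(m) != 2L) stop_fk("pyramid_dim: 2D only")
  if (min(dim(m)) < 8L) stop_fk("pyramid_dim: sides must be >= 8")
  if (sum(m) == 0L) stop_fk("pyramid_dim: empty foreground")
  scales <- dyadic_scales(min(dim(m)))
  cur <- unclass(m)
  counts <- numeric(length(scales))
  counts[1L] <- sum(cur)
  for (i in seq_along(scales)[-1L]) {
    cur <- tile_reduce(cur, 2L, "max")
    counts[i] <- sum(cur)
  }
  series <- scale_series(scales, counts)
  w <- default_window(length(scales))
  fit <- loglog_fit(series, reg_min %||% w[1L], reg_max %||% w[2L])
  new_dimension_result(-fit$slope, fit, "pyramid", list(), series)
}

#' Minkowski (dilation) fractal dimension (2D)
#'
#' Dilates the mask with square (2r+1)^2 structuring elements for
#' r = 1..r_max; the dilated area A(r) grows as r^(2 - D), so
#' D = 2 - slope of ln A(r) vs ln r.
#'
#' @param mask a `binary_mask` (2D).
#' @param r_max largest dilation radius, default 8.
#' @param reg_min,reg_max regression window over r = 1..r_max (default:
#'   full range).
#' @return A `dimension_result`.
#' @export
minkowski_dim <- function(mask, r_max = 8L, reg_min = 1L, reg_max = r_max) {
  m <- as_mask(mask)
  if (grid_rank(m) != 2L) stop_fk("minkowski_dim: 2D only")
  if (sum(m) == 0L) stop_fk("minkowski_dim: empty foreground")
  areas <- vapply(seq_len(r_max), function(r) sum(dilate_square(unclass(m), r)), 0)
  series <- scale_series(seq_len(r_max), areas)
  fit <- loglog_fit(series, reg_min, reg_max)
  new_dimension_result(2 - fit$slope, fit, "minkowski",
                       list(r_max = r_max), series)
}

#' Correlation dimension of a binary mask (2D)
#'
#' Computes the correlation sum C(r) — the fraction of foreground pixel
#' pairs closer than r — over log-spaced radii, and fits its log-log
#' slope. Foreground sets larger than `max_points` are subsampled
#' uniformly (seeded).
#'
#' @param mask a `binary_mask` with >= 10 foreground pixels.
#' @param n_radii number of log-spaced radii, default 12.
#' @param max_points subsampling cap, default 5000.
#' @param reg_min,reg_max regression window; defaults to the central region.
#' @param seed integer seed for the subsample.
#' @return A `dimension_result`.
#' @export
correlation_dim <- function(mask, n_radii = 12L, max_points = 5000L,
                            reg_min = NULL, reg_max = NULL, seed = 1L) {
  m <- as_mask(mask)
  if (grid_rank(m) != 2L) stop_fk("correlation_dim: 2D only")
  pts <- which(unclass(m) > 0, arr.ind = TRUE)
  if (nrow(pts) < 10L) stop_fk("correlation_dim: too few foreground pixels")
  if (nrow(pts) > max_points) {
    keep <- with_seed(seed, sample.int(nrow(pts), max_points))
    pts <- pts[keep, , drop = FALSE]
  }
  dm <- as.vector(stats::dist(pts))
  dmax <- max(dm)
  if (dmax == 0) stop_fk("correlation_dim: degenerate point set (zero extent)")
  # default radii stop at dmax/4: beyond that C(r) saturates towards 1 and
  # the log-log slope flattens regardless of the set's dimension
  r_lo <- max(1.5, min(dm[dm > 0]))
  r_hi <- max(dmax / 4, 2 * r_lo)
  radii <- exp(seq(log(r_lo), log(r_hi), length.out = n_radii))
  Cr <- vapply(radii, function(r) mean(dm < r), 0)
  ok <- Cr > 0
  series <- scale_series(radii[ok], Cr[ok])
  mlen <- length(series$scales)
  if (mlen < 2L) stop_fk("correlation_dim: degenerate regression")
  fit <- loglog_fit(series, reg_min %||% 1L, reg_max %||% mlen)
  new_dimension_result(fit$slope, fit, "correlation",
                       list(n_points = nrow(pts)), series)
}

#' Generalized (Renyi) dimensions D_q of a grey image
#'
#' Normalizes box masses mu_i (grey sums per eps-box over the total mass)
#' on the dyadic scale ladder. For q != 1, D_q is 1/(q-1) times the slope
#' of ln sum(mu^q) vs ln eps; D_1 uses the slope of sum(mu ln mu) vs
#' ln eps. Empty boxes are excluded from the sums.
#'
#' @param grid a [grey_grid()] (2D) with positive total mass.
#' @param q_list moment orders, default c(-2, 0, 1, 2, 4).
#' @param reg_min,reg_max regression window; defaults to the central region.
#' @return Named list of `dimension_result`s, one per q.
#' @export
generalized_dims <- function(grid, q_list = c(-2, 0, 1, 2, 4),
                             reg_min = NULL, reg_max = NULL) {
  x <- unclass(grid) * 1.0
  if (grid_rank(grid) != 2L) stop_fk("generalized_dims: 2D only")
  tot <- sum(x)
  if (tot <= 0) stop_fk("generalized_dims: zero total mass")
  scales <- dyadic_scales(min(dim(x)))
  masses <- lapply(scales, function(e) {
    mu <- as.vector(tile_reduce(x, e, "sum")) / tot
    mu[mu > 0]
  })
  w <- default_window(length(scales))
  out <- lapply(q_list, function(q) {
    if (abs(q - 1) < 1e-12) {
      y <- vapply(masses, function(mu) sum(mu * log(mu)), 0)
      # D1: slope of sum(mu ln mu) vs ln eps, fitted linearly
      lx <- log(scales); rmin <- reg_min %||% w[1L]; rmax <- reg_max %||% w[2L]
      idx <- rmin:rmax
      fit0 <- stats::lm.fit(cbind(1, lx[idx]), y[idx])
      slope <- unname(fit0$coefficients[2L])
      ss_tot <- sum((y[idx] - mean(y[idx]))^2)
      r2 <- if (ss_tot == 0) 1 else 1 - sum(fit0$residuals^2) / ss_tot
      fit <- structure(list(slope = slope,
                            intercept = unname(fit0$coefficients[1L]),
                            r_squared = max(0, min(1, r2)),
                            reg_min = rmin, reg_max = rmax,
                            n_points = length(idx)), class = "scaling_fit")
      new_dimension_result(slope, fit, "generalized_dim", list(q = 1))
    } else {
      y <- vapply(masses, function(mu) sum(mu^q), 0)
      series <- scale_series(scales, y)
      fit <- loglog_fit(series, reg_min %||% w[1L], reg_max %||% w[2L])
      new_dimension_result(fit$slope / (q - 1), fit, "generalized_dim",
                           list(q = q), series)
    }
  })
  names(out) <- paste0("q", q_list)
  out
}

#' FFT (spectral) fractal dimension of an image or volume
#'
#' Estimates the radial power-law exponent beta of the grid's power
#' spectrum (circular average in 2D, spherical average in 3D, see
#' [radial_power_average()]) and converts it to a fractal dimension by
#' D = (3E + 2 - beta)/2, i.e. (8 - beta)/2 for images and (11 - beta)/2
#' for volumes.
#'
#' @param grid a [grey_grid()] (2D or 3D).
#' @param reg_min,reg_max regression window over the radial bins; default
#'   the full range.
#' @param window `"hanning"` (default) or `"none"`.
#' @return A `dimension_result` with extras `beta`.
#' @export
fft_dim_grid <- function(grid, reg_min = 1L, reg_max = NULL,
                         window = c("hanning", "none")) {
  window <- match.arg(window)
  E <- grid_rank(grid)
  series <- radial_power_average(grid, window)
  reg_max <- as.integer(reg_max %||% length(series$scales))
  fit <- loglog_fit(series, reg_min, reg_max, skip_zero = TRUE)
  beta <- -fit$slope
  D <- (3 * E + 2 - beta) / 2
  new_dimension_result(D, fit, "fft", list(window = window, E = E),
                       series, list(beta = beta))
}

#' Higuchi-type fractal dimension of a grey image or volume
#'
#' Two variants. `"profiles_1d"` (2D only) runs the genuine 1D Higuchi
#' algorithm on every row and every column profile and reports the mean
#' profile dimension plus 1 (embedding a D in \[1, 2\] profile into the
#' \[2, 3\] surface range). `"direct_differences"` (2D or 3D) averages the
#' absolute k-spaced grey differences along each axis and normalizes the
#' length measure as L(k) = mean|diff_k| * k^-(E+1), calibrated so that a
#' plane ramp yields exactly D = E; the dimension is minus the log-log
#' slope, in \[E, E+1\].
#'
#' @param grid a [grey_grid()].
#' @param kmax maximum delay, default 8.
#' @param variant `"direct_differences"` (default) or `"profiles_1d"`.
#' @param reg_min,reg_max regression window over k = 1..kmax.
#' @return A `dimension_result`.
#' @export
higuchi_dim_grid <- function(grid, kmax = 8L,
                             variant = c("direct_differences", "profiles_1d"),
                             reg_min = 1L, reg_max = kmax) {
  variant <- match.arg(variant)
  x <- unclass(grid) * 1.0
  E <- grid_rank(grid)
  if (min(dim(x)) < 2L * kmax)
    stop_fk("higuchi_dim_grid: sides must be >= 2*kmax")
  if (variant == "profiles_1d") {
    if (E != 2L) stop_fk("higuchi_dim_grid: profiles_1d is 2D only")
    dims <- c(
      apply(x, 1L, function(p) higuchi_dim_1d(p, kmax, reg_min, reg_max)$dimension),
      apply(x, 2L, function(p) higuchi_dim_1d(p, kmax, reg_min, reg_max)$dimension))
    return(new_dimension_result(mean(dims) + 1, NULL, "higuchi_profiles",
                                list(kmax = kmax, n_profiles = length(dims))))
  }
  L <- vapply(seq_len(kmax), function(k) {
    diffs <- numeric(E)
    for (ax in seq_len(E)) {
      n <- dim(x)[ax]
      i1 <- slice_index(dim(x), ax, (1L + k):n)
      i0 <- slice_index(dim(x), ax, 1:(n - k))
      diffs[ax] <- mean(abs(x[i1] - x[i0]))
    }
    mean(diffs) * k^(-(E + 1))
  }, 0)
  if (all(L == 0)) stop_fk("higuchi_dim_grid: constant grid (degenerate)")
  series <- scale_series(seq_len(kmax), L)
  fit <- loglog_fit(series, reg_min, reg_max)
  new_dimension_result(-fit$slope, fit, "higuchi_direct",
                       list(kmax = kmax, E = E), series)
}

# Index helper: logical array selecting positions range `rng` on axis `ax`.
slice_index <- function(d, ax, rng) {
  idx <- lapply(seq_along(d), function(a) if (a == ax) rng else seq_len(d[a]))
  arr <- array(FALSE, dim = d)
  if (length(d) == 2L) arr[idx[[1L]], idx[[2L]]] <- TRUE
  else arr[idx[[1L]], idx[[2L]], idx[[3L]]] <- TRUE
  arr
}

#' Lacunarity of a binary mask (2D)
#'
#' For each box size r, computes box masses M (foreground counts) over
#' non-overlapping raster tiles or gliding (step 1, fully inside) windows
#' and reports Lambda(r) = <M^2> / <M>^2. Lambda >= 1, with larger values
#' for gappier spatial arrangements.
#'
#' @param mask a `binary_mask` (2D), nonempty foreground.
#' @param box_sizes increasing positive box sizes; default dyadic up to a
#'   quarter of the smallest side.
#' @param mode `"gliding"` (default) or `"raster"`.
#' @return A `lacunarity_series` list with `box_sizes`, `lacunarity`,
#'   `mode`.
#' @export
lacunarity <- function(mask, box_sizes = NULL, mode = c("gliding", "raster")) {
  mode <- match.arg(mode)
  m <- as_mask(mask)
  if (grid_rank(m) != 2L) stop_fk("lacunarity: 2D only")
  if (sum(m) == 0L) stop_fk("lacunarity: empty foreground")
  d <- dim(m)
  box_sizes <- box_sizes %||% dyadic_scales(min(d) %/% 2L)
  if (any(box_sizes > min(d))) stop_fk("lacunarity: box larger than image")
  lam <- vapply(box_sizes, function(r) {
    M <- if (mode == "raster") as.vector(tile_reduce(unclass(m), r, "sum"))
         else as.vector(gliding_sums(unclass(m), r))
    mean(M^2) / mean(M)^2
  }, 0)
  structure(list(box_sizes = box_sizes, lacunarity = lam, mode = mode),
            class = "lacunarity_series")
}

#' @export
print.lacunarity_series <- function(x, ...) {
  cat(sprintf("<lacunarity_series (%s), r = %s, Lambda = %s>\n", x$mode,
              paste(x$box_sizes, collapse = ","),
              paste(sprintf("%.3f", x$lacunarity), collapse = ",")))
  invisible(x)
}

# All r x r window sums fully inside the image, via an integral image.
gliding_sums <- function(m, r) {
  d <- dim(m)
  S <- matrix(0, d[1L] + 1L, d[2L] + 1L)
  S[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  i <- seq_len(d[1L] - r + 1L); j <- seq_len(d[2L] - r + 1L)
  S[i + r, j + r] - S[i, j + r] - S[i + r, j] + S[i, j]
}

#' Fractal fragmentation index (FFI)
#'
#' FFI = D_area - D_perimeter: the box-counting dimension of the mask minus
#' that of its boundary (foreground minus its 4-connected erosion). Near 1
#' for compact Euclidean objects, 0 for fully fragmented dust (where the
#' boundary equals the object).
#'
#' @param mask a `binary_mask` (2D), nonempty foreground.
#' @return A `dimension_result` with `dimension` = FFI and extras `d_area`,
#'   `d_perimeter`.
#' @export
ffi <- function(mask) {
  m <- as_mask(mask)
  if (grid_rank(m) != 2L) stop_fk("ffi: 2D only")
  if (sum(m) == 0L) stop_fk("ffi: empty foreground")
  if (sum(m) == 1L)
    stop_fk("ffi: single-pixel foreground (boundary dimension undefined)")
  core <- erode_cross(unclass(m))
  boundary <- unclass(m) - core
  if (sum(boundary) == 0L) stop_fk("ffi: empty boundary")
  d_area <- box_counting_dim(structure(unclass(m), class = "binary_mask",
                                       threshold = 0))$dimension
  d_perim <- box_counting_dim(structure(boundary, class = "binary_mask",
                                        threshold = 0))$dimension
  new_dimension_result(d_area - d_perim, NULL, "ffi", list(),
                       extra = list(d_area = d_area, d_perimeter = d_perim))
}
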