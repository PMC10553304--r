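# Naive brute-force reference implementations, kept deliberately dumb and
# independent of the package's vectorised code paths.

bf_higuchi_series <- function(x, kmax) {
  N <- length(x)
  L <- numeric(kmax)
  for (k in seq_len(kmax)) {
    Lm <- numeric(k)
    for (m in seq_len(k)) {
      n_m <- floor((N - m) / k)
      s <- 0
      for (i in seq_len(n_m)) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      Lm[m] <- (s * (N - 1) / (n_m * k)) / k
    }
    L[k] <- mean(Lm)
  }
  L
}

bf_ols_loglog <- function(s, M) {
  x <- log(s); y <- log(M)
  n <- length(x)
  sl <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  ic <- mean(y) - sl * mean(x)
  yhat <- ic + sl * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = sl, intercept = ic, r_squared = r2)
}

bf_box_counts <- function(mask, scales) {
  d <- dim(mask)
  vapply(scales, function(e) {
    cnt <- 0
    for (i0 in seq(1, d[1], by = e)) for (j0 in seq(1, d[2], by = e)) {
      blk <- mask[i0:min(i0 + e - 1, d[1]), j0:min(j0 + e - 1, d[2])]
      if (any(blk > 0)) cnt <- cnt + 1
    }
    cnt
  }, 0)
}

bf_lacunarity <- function(mask, r, mode) {
  d <- dim(mask)
  M <- c()
  if (mode == "raster") {
    for (i0 in seq(1, d[1], by = r)) for (j0 in seq(1, d[2], by = r)) {
      blk <- mask[i0:min(i0 + r - 1, d[1]), j0:min(j0 + r - 1, d[2])]
      M <- c(M, sum(blk))
    }
  } else {
    for (i0 in seq_len(d[1] - r + 1)) for (j0 in seq_len(d[2] - r + 1)) {
      M <- c(M, sum(mask[i0:(i0 + r - 1), j0:(j0 + r - 1)]))
    }
  }
  mean(M^2) / mean(M)^2
}

bf_apen <- function(x, m, r) {
  N <- length(x)
  phi <- function(mm) {
    nt <- N - mm + 1
    C <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) cnt <- cnt + 1
      }
      C[i] <- cnt / nt
    }
    mean(log(C))
  }
  phi(m) - phi(m + 1)
}

bf_sampen <- function(x, m, r) {
  N <- length(x)
  nt <- N - m
  cnt <- function(mm) {
    s <- 0
    for (i in seq_len(nt)) for (j in seq_len(nt)) {
      if (i != j && max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
        s <- s + 1
    }
    s
  }
  -log(cnt(m + 1) / cnt(m))
}

# direct loop evaluation of the generalized-entropy formulas
bf_entropies <- function(p, q, kappa, b, beta, gamma) {
  p <- p[p > 0]
  se <- 0; for (pi in p) se <- se - pi * log(pi)
  sq <- 0; for (pi in p) sq <- sq + pi^q
  renyi <- if (q == 1) se else log(sq) / (1 - q)
  tsallis <- if (q == 1) se else (1 - sq) / (q - 1)
  snorm <- if (q == 1) se else tsallis / sq
  sescort <- if (q == 1) se else {
    esc <- p^q / sq
    v <- 0; for (e in esc) v <- v - e * log(e); v
  }
  skappa <- 0; for (pi in p) skappa <- skappa - pi * (pi^kappa - pi^(-kappa)) / (2 * kappa)
  sb <- exp(-b) - 1; for (pi in p) sb <- sb + (1 - exp(-b * pi))
  sbeta <- 0; for (pi in p) sbeta <- sbeta - pi^beta * log(pi)
  sgamma <- 0; for (pi in p) sgamma <- sgamma + pi^(1 / gamma) * log(1 / pi)
  list(shannon = se, renyi = renyi, tsallis = tsallis, snorm = snorm,
       sescort = sescort, skappa = skappa, sb = sb, sbeta = sbeta,
       sgamma = sgamma)
}

make_mask <- function(m01) binarize(grey_grid(m01 * 255))

random_mask <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, matrix(stats::rbinom(n * n, 1, p), n, n))
}
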