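# Entropy measures and compression-based complexity.

#' Empirical probability distribution of a sequence or grid
#'
#' Sequences are binned into `bins` equal-width bins over \[min, max\];
#' grids default to 256 grey bins over \[0, 255\]. Empty bins are retained
#' with p = 0 (entropy sums skip them where ln p appears).
#'
#' @param data numeric vector or [grey_grid()].
#' @param bins number of bins (default 256).
#' @return A `prob_dist` list with `p` (probabilities summing to 1),
#'   `breaks` and `counts`.
#' @export
histogram_probs <- function(data, bins = 256L) {
  x <- if (inherits(data, "grey_grid")) as.vector(unclass(data)) else as.numeric(data)
  if (length(x) == 0L) stop_fk("histogram_probs: empty data")
  bins <- as.integer(bins)
  if (bins < 1L) stop_fk("histogram_probs: bins must be >= 1")
  if (inherits(data, "grey_grid")) {
    breaks <- seq(0, 255, length.out = bins + 1L)
  } else {
    rng <- range(x)
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  }
  idx <- pmin(bins, pmax(1L, findInterval(x, breaks, rightmost.closed = TRUE)))
  counts <- tabulate(idx, nbins = bins)
  structure(list(p = counts / sum(counts), breaks = breaks, counts = counts),
            class = "prob_dist")
}

#' @export
print.prob_dist <- function(x, ...) {
  cat(sprintf("<prob_dist, %d bins, %d occupied>\n",
              length(x$p), sum(x$p > 0)))
  invisible(x)
}

as_probs <- function(dist) {
  p <- if (inherits(dist, "prob_dist")) dist$p else as.numeric(dist)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_fk("generalized_entropies: probabilities must be nonnegative and sum to 1")
  p
}

# Template match counts shared by ApEn / SampEn: for embedding dimension m,
# counts[i] = number of j with Chebyshev distance between the length-m
# templates at i and j not exceeding r.
template_counts <- function(x, m, r, include_self) {
  N <- length(x)
  nt <- N - m + 1L
  cnt <- rep(if (include_self) 0L else 0L, nt)
  # pairwise max over the m lagged absolute-difference matrices
  D <- abs(outer(x[seq_len(nt)], x[seq_len(nt)], `-`))
  if (m > 1L) for (l in seq_len(m - 1L)) {
    idx <- seq_len(nt) + l
    D <- pmax(D, abs(outer(x[idx], x[idx], `-`)))
  }
  match <- D <= r
  if (!include_self) diag(match) <- FALSE
  rowSums(match)
}

resolve_r <- function(x, r, relative) {
  if (!relative) return(r)
  s <- stats::sd(x)
  if (s == 0) stop_fk("entropy: zero SD with relative tolerance r")
  r * s
}

#' Approximate entropy (ApEn)
#'
#' Pincus's ApEn(m, r, N) = Phi_m(r) - Phi_(m+1)(r), where Phi_m is the
#' mean over templates of ln(fraction of templates within Chebyshev
#' distance r), self-matches included.
#'
#' @param seq numeric vector, length >= m + 2.
#' @param m template length, default 2.
#' @param r tolerance; with `relative = TRUE` (default) it is `r * sd(seq)`.
#' @param relative interpret `r` as a multiple of the sample SD.
#' @return Single real.
#' @export
approximate_entropy <- function(seq, m = 2L, r = 0.2, relative = TRUE) {
  x <- as.numeric(seq)
  N <- length(x)
  m <- as.integer(m)
  if (N < m + 2L) stop_fk("approximate_entropy: need N >= m + 2")
  r <- resolve_r(x, r, relative)
  phi <- function(mm) {
    cnt <- template_counts(x, mm, r, include_self = TRUE)
    mean(log(cnt / (N - mm + 1L)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (SampEn)
#'
#' Richman-Moorman SampEn = -ln(A / B), where B counts template pairs
#' (i != j) matching at length m and A those matching at length m + 1,
#' self-matches excluded. Both counts use the N - m templates that have an
#' m+1 continuation.
#'
#' @inheritParams approximate_entropy
#' @return Single real.
#' @export
sample_entropy <- function(seq, m = 2L, r = 0.2, relative = TRUE) {
  x <- as.numeric(seq)
  N <- length(x)
  m <- as.integer(m)
  if (N < m + 2L) stop_fk("sample_entropy: need N >= m + 2")
  r <- resolve_r(x, r, relative)
  nt <- N - m                         # templates with an m+1 continuation
  B <- pair_count(x, m, r, nt)
  A <- pair_count(x, m + 1L, r, nt)
  if (A == 0 || B == 0) stop_fk("sample_entropy: undefined (no matches)")
  -log(A / B)
}

pair_count <- function(x, m, r, nt) {
  D <- abs(outer(x[seq_len(nt)], x[seq_len(nt)], `-`))
  if (m > 1L) for (l in seq_len(m - 1L)) {
    idx <- seq_len(nt) + l
    D <- pmax(D, abs(outer(x[idx], x[idx], `-`)))
  }
  match <- D <= r
  diag(match) <- FALSE
  sum(match)
}

#' Permutation entropy
#'
#' Bandt-Pompe ordinal-pattern entropy: each length-`order` template (with
#' spacing `delay`) is mapped to the permutation that sorts it (ties broken
#' by earlier index first), and the Shannon entropy of the pattern
#' distribution is reported in nats (`variant = "raw"`), divided by
#' order - 1 (`"per_symbol"`), or by ln(order!) (`"normalized"`, in
#' \[0, 1\]).
#'
#' @param seq numeric vector, length >= order * delay + 1.
#' @param order pattern length, 2..8 (default 3).
#' @param delay lag between template samples, default 1.
#' @param variant `"raw"`, `"per_symbol"` or `"normalized"`.
#' @return Single real.
#' @export
permutation_entropy <- function(seq, order = 3L, delay = 1L,
                                variant = c("raw", "per_symbol", "normalized")) {
  variant <- match.arg(variant)
  x <- as.numeric(seq)
  N <- length(x)
  order <- as.integer(order); delay <- as.integer(delay)
  if (order < 2L || order > 8L) stop_fk("permutation_entropy: order must be in [2, 8]")
  if (N < order * delay + 1L) stop_fk("permutation_entropy: sequence too short")
  nt <- N - (order - 1L) * delay
  emb <- sapply(seq_len(order), function(j) x[(seq_len(nt)) + (j - 1L) * delay])
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1L)
  # encode each template's ordinal pattern by its pairwise comparisons;
  # ties resolve earlier-index-first (strict > keeps the earlier element
  # in front), so the code is a bijection onto ordinal patterns
  pairs <- utils::combn(order, 2L)
  code <- numeric(nt)
  for (pc in seq_len(ncol(pairs))) {
    code <- code + (emb[, pairs[1L, pc]] > emb[, pairs[2L, pc]]) * 2^(pc - 1L)
  }
  p <- table(code) / nt
  H <- -sum(p * log(p))
  switch(variant,
    raw = H,
    per_symbol = H / (order - 1L),
    normalized = H / log(factorial(order)))
}

#' Generalized entropies of a probability distribution
#'
#' Evaluates a family of entropy functionals per order q (sums run over
#' p > 0): Shannon SE = -sum p ln p; Renyi_q = ln(sum p^q)/(1-q);
#' Tsallis_q = (1 - sum p^q)/(q-1); SNorm_q = Tsallis_q / sum p^q;
#' SEscort_q = Shannon entropy of the escort distribution p^q / sum p^q;
#' SKappa_k = -sum p (p^k - p^-k)/(2k); SB_b = sum(1 - exp(-b p)) +
#' (exp(-b) - 1); SBeta_b = -sum p^b ln p; SGamma_g = sum p^(1/g) ln(1/p).
#' Renyi and Tsallis return the Shannon limit at q = 1; SKappa returns
#' Shannon at kappa = 0.
#'
#' @param dist a `prob_dist` (or bare probability vector).
#' @param q_list orders for the q-indexed families, default
#'   c(0.5, 1, 2, 4).
#' @param kappa,b,beta,gamma parameters of the SKappa, SB, SBeta and
#'   SGamma functionals (defaults 0.5, 1, 0.5, 2).
#' @return Data frame: one row per q with columns `q`, `renyi`, `tsallis`,
#'   `snorm`, `sescort`, plus the q-independent `shannon`, `skappa`, `sb`,
#'   `sbeta`, `sgamma` repeated on each row.
#' @export
generalized_entropies <- function(dist, q_list = c(0.5, 1, 2, 4),
                                  kappa = 0.5, b = 1, beta = 0.5, gamma = 2) {
  p <- as_probs(dist)
  pp <- p[p > 0]
  shannon <- -sum(pp * log(pp))
  skappa <- if (abs(kappa) < 1e-12) shannon
            else -sum(pp * (pp^kappa - pp^(-kappa)) / (2 * kappa))
  sb <- sum(1 - exp(-b * pp)) + (exp(-b) - 1)
  sbeta <- -sum(pp^beta * log(pp))
  sgamma <- sum(pp^(1 / gamma) * log(1 / pp))
  rows <- lapply(q_list, function(q) {
    if (abs(q - 1) < 1e-12) {
      renyi <- tsallis <- shannon
      snorm <- shannon
      sescort <- shannon
    } else {
      sq <- sum(pp^q)
      renyi <- log(sq) / (1 - q)
      tsallis <- (1 - sq) / (q - 1)
      snorm <- tsallis / sq
      esc <- pp^q / sq
      sescort <- -sum(esc * log(esc))
    }
    data.frame(q = q, shannon = shannon, renyi = renyi, tsallis = tsallis,
               snorm = snorm, sescort = sescort, skappa = skappa, sb = sb,
               sbeta = sbeta, sgamma = sgamma)
  })
  do.call(rbind, rows)
}

#' Compression-based Kolmogorov complexity and logical depth
#'
#' Serializes the data to a canonical byte stream (sequences: 8-byte IEEE
#' doubles in order; grids: row-major 8-bit grey after rounding), and
#' reports the length of its losslessly compressed representation (an
#' upper-bound proxy for algorithmic complexity) plus a logical-depth
#' proxy: the median wall time of repeated decompressions. Both the
#' `"zlib"` and `"gzip"` compressor names select the DEFLATE algorithm of
#' base R's `memCompress()`. Logical depth is hardware dependent and
#' flagged as such.
#'
#' @param data numeric vector or [grey_grid()].
#' @param compressor `"gzip"` (default) or `"zlib"` (both DEFLATE).
#' @param ld_iterations decompression repetitions for the logical-depth
#'   median, default 10.
#' @return One-row data frame: `original_bytes`, `compressed_bytes` (KC),
#'   `ratio`, `logical_depth_s`, `hardware_dependent`.
#' @export
kolmogorov_complexity <- function(data, compressor = c("gzip", "zlib"),
                                  ld_iterations = 10L) {
  compressor <- match.arg(compressor)
  if (inherits(data, "grey_grid")) {
    bytes <- as.raw(round_half_up(as.vector(aperm_rowmajor(unclass(data)))))
  } else {
    x <- as.numeric(data)
    if (length(x) == 0L) stop_fk("kolmogorov_complexity: empty data")
    bytes <- writeBin(x, raw(), size = 8L, endian = "little")
  }
  comp <- memCompress(bytes, type = "gzip")
  times <- vapply(seq_len(max(1L, ld_iterations)), function(i) {
    t0 <- proc.time()[["elapsed"]]
    invisible(memDecompress(comp, type = "gzip"))
    proc.time()[["elapsed"]] - t0
  }, 0)
  data.frame(original_bytes = length(bytes),
             compressed_bytes = length(comp),
             ratio = length(comp) / length(bytes),
             compressor = compressor,
             logical_depth_s = stats::median(times),
             hardware_dependent = TRUE)
}

# row-major flattening for serialization (R arrays are column-major)
aperm_rowmajor <- function(a) {
  d <- dim(a)
  aperm(a, rev(seq_along(d)))
}
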