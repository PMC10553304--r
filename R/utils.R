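# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. seed = NULL draws an entropy-sourced seed and returns it via the
# "seed_used" attribute so callers can record provenance.
with_seed <- function(seed, expr) {
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  out <- withr::with_seed(as.integer(seed), expr)
  attr(out, "seed_used") <- as.integer(seed)
  out
}

# Derive `n` child seeds from a base seed, for independent surrogate draws.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

stop_fk <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Round half away from zero (classic 8-bit quantization; R's round() is
# banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

# Pad an array with zeros (or `fill`) so every side is a multiple of eps.
pad_to_multiple <- function(a, eps, fill = 0) {
  d <- dim(a) %||% length(a)
  nd <- as.integer(ceiling(d / eps) * eps)
  if (all(nd == d)) return(a)
  out <- array(fill, dim = nd)
  idx <- lapply(d, seq_len)
  out[do.call(cbind, expand_indices(idx))] <- a
  out
}

expand_indices <- function(idx) {
  g <- do.call(expand.grid, c(idx, KEEP.OUT.ATTRS = FALSE))
  as.list(g)
}

# Aggregate an E-dim array over eps-sided tiles anchored at the origin with
# function `fun` ("sum" or "max"). Partial tiles at the far edges are kept
# (padded with zeros). Returns the reduced array.
tile_reduce <- function(a, eps, fun = c("sum", "max")) {
  fun <- match.arg(fun)
  if (eps == 1L) return(a)
  a <- pad_to_multiple(a, eps)
  d <- dim(a) %||% length(a)
  for (ax in seq_along(d)) {
    a <- reduce_axis(a, ax, eps, fun)
  }
  a
}

# Collapse axis `ax` of array `a` by grouping eps consecutive entries.
reduce_axis <- function(a, ax, eps, fun) {
  d <- dim(a) %||% length(a)
  perm <- c(ax, seq_along(d)[-ax])
  if (length(d) > 1L) a <- aperm(a, perm)
  m <- matrix(a, nrow = d[ax])
  ng <- d[ax] %/% eps
  # view as eps x (ng * ncol) so colSums/colMax collapse each tile strip
  m2 <- matrix(m, nrow = eps)
  red <- if (fun == "sum") colSums(m2) else apply_colmax(m2)
  newd <- d
  newd[ax] <- ng
  out <- array(red, dim = newd[perm])
  if (length(d) > 1L) out <- aperm(out, order(perm))
  out
}

apply_colmax <- function(m) {
  out <- m[1L, ]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) out <- pmax(out, m[i, ])
  out
}

# Shift a matrix/array by integer offsets, filling vacated cells with `fill`.
shift_array <- function(a, offsets, fill = 0) {
  d <- dim(a)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", length(d))
  for (ax in seq_along(d)) {
    o <- offsets[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) {
      src[[ax]] <- seq_len(d[ax] - o)
      dst[[ax]] <- seq_len(d[ax] - o) + o
    } else {
      src[[ax]] <- seq_len(d[ax] + o) - o
      dst[[ax]] <- seq_len(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  out
}

# Square (2r+1)^2 binary dilation by separable running max (axis shifts).
dilate_square <- function(mask, r) {
  out <- mask
  for (o in seq_len(r)) {
    out <- pmax(out, shift_array(mask, c(o, 0)), shift_array(mask, c(-o, 0)))
  }
  mask2 <- out
  for (o in seq_len(r)) {
    out <- pmax(out, shift_array(mask2, c(0, o)), shift_array(mask2, c(0, -o)))
  }
  out
}

# 4-connected binary erosion (pixels whose N/S/E/W neighbours are all set;
# image border counts as background).
erode_cross <- function(mask) {
  pmin(mask,
       shift_array(mask, c(1, 0)), shift_array(mask, c(-1, 0)),
       shift_array(mask, c(0, 1)), shift_array(mask, c(0, -1)))
}
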