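#' Grey-value grid (2D image or 3D volume)
#'
#' Light container for 8-bit grey data. A `grey_grid` is a plain numeric
#' matrix (2D: rows x columns) or 3-way array (3D: rows x columns x slices)
#' with values in \[0, 255\], carrying the class attribute so estimators can
#' dispatch on it. All internal computation is double precision; the 8-bit
#' range is a storage convention.
#'
#' @param data numeric matrix or 3-way array with values in \[0, 255\].
#' @return A `grey_grid` object.
#' @export
grey_grid <- function(data) {
  if (is.null(dim(data)) || !(length(dim(data)) %in% c(2L, 3L)))
    stop_fk("grey_grid: data must be a matrix or 3-way array")
  if (any(dim(data) < 1L)) stop_fk("grey_grid: all dimensions must be >= 1")
  if (anyNA(data) || min(data) < 0 || max(data) > 255)
    stop_fk("grey_grid: values must be finite and within [0, 255]")
  structure(data, class = "grey_grid")
}

#' @export
print.grey_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<grey_grid %s, grey range [%g, %g]>\n",
              paste(d, collapse = "x"), min(x), max(x)))
  invisible(x)
}

grid_rank <- function(grid) length(dim(grid))

#' Binarize a grey grid
#'
#' Produces a binary mask with value 1 where grey exceeds `threshold`,
#' else 0. The default threshold 0 makes any nonzero grey foreground,
#' matching the convention of set-based estimators (box counting,
#' lacunarity, fragmentation index).
#'
#' @param grid a [grey_grid()] (or plain matrix/array).
#' @param threshold real; foreground is `grey > threshold`. Default 0.
#' @return A `binary_mask`: 0/1 array of the same shape, with the threshold
#'   stored in the `"threshold"` attribute.
#' @export
binarize <- function(grid, threshold = 0) {
  m <- (unclass(grid) > threshold) * 1L
  dim(m) <- dim(grid)
  structure(m, threshold = threshold, class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %s, %d foreground, threshold %g>\n",
              paste(dim(x), collapse = "x"), sum(x),
              attr(x, "threshold")), sep = "")
  invisible(x)
}

as_mask <- function(x, threshold = 0) {
  if (inherits(x, "binary_mask")) x else binarize(x, threshold)
}

#' Scale series: paired (scale, measure) points for log-log regression
#'
#' @param scales strictly increasing positive reals.
#' @param measures real measures, one per scale (non-positive entries are
#'   handled by the regression's skip-zero policy).
#' @return A `scale_series` list with elements `scales` and `measures`.
#' @export
scale_series <- function(scales, measures) {
  if (length(scales) != length(measures))
    stop_fk("scale_series: scales and measures differ in length")
  if (length(scales) < 2L) stop_fk("scale_series: need at least 2 points")
  if (any(scales <= 0) || any(diff(scales) <= 0))
    stop_fk("scale_series: scales must be positive and strictly increasing")
  structure(list(scales = as.numeric(scales), measures = as.numeric(measures)),
            class = "scale_series")
}

#' @export
print.scale_series <- function(x, ...) {
  cat(sprintf("<scale_series, %d points, scales %g..%g>\n",
              length(x$scales), min(x$scales), max(x$scales)))
  invisible(x)
}

new_dimension_result <- function(dimension, fit = NULL, method, params = list(),
                                 series = NULL, extra = list()) {
  structure(c(list(dimension = dimension, fit = fit, method = method,
                   params = params, series = series), extra),
            class = "dimension_result")
}

#' @export
print.dimension_result <- function(x, ...) {
  cat(sprintf("<%s dimension estimate: %.4f", x$method, x$dimension))
  if (!is.null(x$fit))
    cat(sprintf("  (slope %.4f, R2 %.4f, window [%d, %d])",
                x$fit$slope, x$fit$r_squared, x$fit$reg_min, x$fit$reg_max))
  cat(">\n")
  invisible(x)
}

#' Summarize a surrogate ensemble
#'
#' @param original_value statistic on the original data.
#' @param surrogate_values statistic on each surrogate.
#' @return A `surrogate_report` list with the original value, the individual
#'   surrogate values, and their mean and sample standard deviation
#'   (denominator n - 1).
#' @export
surrogate_report <- function(original_value, surrogate_values) {
  structure(list(original_value = original_value,
                 surrogate_values = as.numeric(surrogate_values),
                 surrogate_mean = mean(surrogate_values),
                 surrogate_sd = stats::sd(surrogate_values)),
            class = "surrogate_report")
}

#' @export
print.surrogate_report <- function(x, ...) {
  cat(sprintf("<surrogate_report: original %.5g, %d surrogates, mean %.5g, sd %.5g>\n",
              x$original_value, length(x$surrogate_values),
              x$surrogate_mean, x$surrogate_sd))
  invisible(x)
}
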