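# Sequence tables, result tables and image/volume readers.
#
# Sequence files are comma separated text: the first row holds column
# headers, the first column holds row headers, data cells are real numbers
# with a point decimal mark, and columns shorter than the table are padded
# at the bottom with the literal token NaN.

#' Read 1D sequences from a comma-separated table
#'
#' Each data column (every column after the row-header column) becomes one
#' sequence. Trailing runs of the token `NaN` pad short columns and are
#' stripped on load; a `NaN` *above* a real value indicates a ragged column
#' and is an error.
#'
#' @param path file path to a comma-separated text file.
#' @return Named list of numeric vectors, one per data column, in file
#'   order.
#' @export
read_sequences_csv <- function(path) {
  if (!file.exists(path)) stop_fk("read_sequences_csv: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_fk("read_sequences_csv: empty table in %s", path)
  cells <- strsplit(lines, ",", fixed = TRUE)
  header <- trimws(cells[[1L]])
  ncol <- length(header)
  if (ncol < 2L) stop_fk("read_sequences_csv: no data columns in %s", path)
  body <- cells[-1L]
  nrow <- length(body)
  vals <- matrix(NA_real_, nrow = nrow, ncol = ncol - 1L)
  for (i in seq_len(nrow)) {
    row <- trimws(body[[i]])
    if (length(row) != ncol)
      stop_fk("read_sequences_csv: row %d has %d cells, expected %d",
              i, length(row), ncol)
    for (j in 2:ncol) {
      tok <- row[j]
      if (toupper(tok) == "NAN") {
        vals[i, j - 1L] <- NaN
      } else {
        v <- suppressWarnings(as.numeric(tok))
        if (is.na(v))
          stop_fk("read_sequences_csv: malformed number '%s' at row %d, column %d",
                  tok, i, j)
        vals[i, j - 1L] <- v
      }
    }
  }
  out <- vector("list", ncol - 1L)
  names(out) <- header[-1L]
  for (j in seq_len(ncol - 1L)) {
    col <- vals[, j]
    nan <- is.nan(col)
    n_keep <- if (any(nan)) min(which(nan)) - 1L else nrow
    if (any(nan[seq_len(n_keep)]) || (n_keep < nrow && !all(nan[(n_keep + 1L):nrow])))
      stop_fk("read_sequences_csv: ragged column '%s' (internal NaN)", header[j + 1L])
    if (n_keep < 1L)
      stop_fk("read_sequences_csv: column '%s' holds no data", header[j + 1L])
    out[[j]] <- col[seq_len(n_keep)]
  }
  out
}

#' Write a result table (or sequences) as comma-separated text
#'
#' Writes the dialect that [read_sequences_csv()] reads back: header row
#' first, row labels in the first column, point decimal mark, and the
#' literal token `NaN` for absent cells (so columns of unequal length can
#' share one table).
#'
#' @param table a data frame, or a named list of numeric vectors (columns
#'   may have different lengths; shorter ones are NaN-padded).
#' @param path output file path.
#' @param row_labels optional character vector of row labels; defaults to
#'   the row number.
#' @return Invisibly, the path.
#' @export
write_table_csv <- function(table, path, row_labels = NULL) {
  if (is.data.frame(table)) table <- as.list(table)
  if (!is.list(table) || length(table) == 0L)
    stop_fk("write_table_csv: table must be a nonempty data frame or named list")
  lens <- vapply(table, length, 1L)
  if (any(lens == 0L)) stop_fk("write_table_csv: empty column")
  n <- max(lens)
  labels <- row_labels %||% as.character(seq_len(n))
  fmt_cell <- function(v) {
    if (is.numeric(v)) {
      out <- vapply(v, function(x) {
        if (is.na(x)) "NaN" else format(x, digits = 17, scientific = FALSE, trim = TRUE)
      }, "")
    } else {
      out <- as.character(v)
      out[is.na(out)] <- "NaN"
    }
    out
  }
  cols <- lapply(table, function(v) {
    c(fmt_cell(v), rep("NaN", n - length(v)))
  })
  header <- paste(c("Row", names(table) %||% paste0("C", seq_along(table))),
                  collapse = ",")
  rows <- vapply(seq_len(n), function(i) {
    paste(c(labels[i], vapply(cols, `[[`, "", i)), collapse = ",")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Read a 2D image or 3D volume as a grey grid
#'
#' Accepts 8-bit grey or 8-bit/channel RGB PNG and TIFF; a multi-page TIFF
#' loads as a 3D grid with the page index as the slice axis. RGB is
#' converted to grey by BT.709 luminance 0.2126 R + 0.7152 G + 0.0722 B,
#' rounded half up.
#'
#' @param path PNG or TIFF file path.
#' @return A [grey_grid()] with values in \[0, 255\]; 2D shape is
#'   (rows, cols), 3D shape is (rows, cols, slices).
#' @export
read_grid <- function(path) {
  if (!file.exists(path)) stop_fk("read_grid: no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
    pages <- list(img)
  } else if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
  } else {
    stop_fk("read_grid: unsupported file type '%s'", ext)
  }
  greys <- lapply(pages, page_to_grey)
  if (length(greys) == 1L) return(grey_grid(greys[[1L]]))
  d <- dim(greys[[1L]])
  if (!all(vapply(greys, function(g) identical(dim(g), d), TRUE)))
    stop_fk("read_grid: pages differ in size")
  grey_grid(array(unlist(greys), dim = c(d, length(greys))))
}

page_to_grey <- function(img) {
  if (length(dim(img)) == 2L) {
    g <- img * 255
  } else if (length(dim(img)) == 3L && dim(img)[3L] %in% c(2L, 3L, 4L)) {
    if (dim(img)[3L] == 2L) {
      g <- img[, , 1L] * 255           # grey + alpha
    } else {
      g <- 255 * (0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] +
                    0.0722 * img[, , 3L])
    }
  } else {
    stop_fk("read_grid: unsupported channel layout")
  }
  if (any(dim(g) < 1L)) stop_fk("read_grid: zero-size image")
  round_half_up(g)
}

#' Write a grey grid as PNG or (multi-page) TIFF
#'
#' @param grid a [grey_grid()]; written as 8-bit grey. 3D grids must go to
#'   TIFF (one page per slice).
#' @param path output path ending in .png, .tif or .tiff.
#' @return Invisibly, the path.
#' @export
write_grid <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  x <- unclass(grid) / 255
  if (grid_rank(grid) == 2L) {
    if (ext == "png") png::writePNG(x, path)
    else if (ext %in% c("tif", "tiff")) tiff::writeTIFF(x, path, bits.per.sample = 8L)
    else stop_fk("write_grid: unsupported file type '%s'", ext)
  } else {
    if (!(ext %in% c("tif", "tiff")))
      stop_fk("write_grid: 3D grids must be written as multi-page TIFF")
    pages <- lapply(seq_len(dim(x)[3L]), function(k) x[, , k])
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  }
  invisible(path)
}
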