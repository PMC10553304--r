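# Sequence CSV dialect, grid I/O, binarization and the CLI dispatcher.

write_lines_tmp <- function(lines) {
  p <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, p)
  p
}

test_that("sequence CSV reader handles headers, row labels and NaN padding", {
  p <- write_lines_tmp(c("Row,a,b", "1,0.5,2", "2,1.5,4", "3,-2.25,6", "4,3e-2,8"))
  s <- read_sequences_csv(p)
  expect_named(s, c("a", "b"))
  expect_equal(s$a, c(0.5, 1.5, -2.25, 0.03))
  expect_equal(s$b, c(2, 4, 6, 8))

  # a column of 3 values padded with 2 trailing NaN in a 5-row table
  p2 <- write_lines_tmp(c("Row,x,y", "1,1,9", "2,2,9", "3,3,9", "4,NaN,9", "5,NaN,9"))
  s2 <- read_sequences_csv(p2)
  expect_length(s2$x, 3L)
  expect_length(s2$y, 5L)
  expect_equal(s2$x, c(1, 2, 3))
})

test_that("sequence CSV reader rejects malformed input with located errors", {
  p <- write_lines_tmp(c("Row,a", "1,0.5", "2,oops"))
  expect_error(read_sequences_csv(p), "row 2, column 2")
  p2 <- write_lines_tmp(c("Row,a", "1,1", "2,NaN", "3,3"))
  expect_error(read_sequences_csv(p2), "ragged column")
  p3 <- write_lines_tmp("Row,a")
  expect_error(read_sequences_csv(p3), "empty")
  expect_error(read_sequences_csv(file.path(tempdir(), "no-such.csv")), "no such file")
})

test_that("result tables round-trip losslessly and NaN-pad ragged columns", {
  p <- withr::local_tempfile(fileext = ".csv")
  vals <- withr::with_seed(42, list(a = stats::rnorm(7) * 1e6,
                                    b = stats::runif(4) * 1e-9))
  write_table_csv(vals, p)
  back <- read_sequences_csv(p)
  expect_identical(back$a, unname(vals$a))   # bit-for-bit
  expect_identical(back$b, unname(vals$b))
  # the short column is padded with the literal token NaN
  lines <- readLines(p)
  expect_match(lines[6], "NaN$")
  expect_equal(length(lines), 8L)            # header + 7 rows

  # a one-row table with named measures
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table_csv(list(Dh = 1.5, R2 = 0.99), p2)
  got <- readLines(p2)
  expect_equal(got[1L], "Row,Dh,R2")
  expect_equal(length(got), 2L)
  expect_error(write_table_csv(list(), p2), "nonempty")
})

test_that("grid reader round-trips 8-bit PNG and multi-page TIFF exactly", {
  g <- generate_image("random", width = 40, height = 32, seed = 11)[[1]]
  p <- withr::local_tempfile(fileext = ".png")
  write_grid(g, p)
  back <- read_grid(p)
  expect_equal(dim(back), c(32L, 40L))
  expect_equal(max(abs(unclass(back) - unclass(g))), 0)

  v <- generate_volume("random", width = 16, height = 12, depth = 9, seed = 3)
  pv <- withr::local_tempfile(fileext = ".tif")
  write_grid(v, pv)
  backv <- read_grid(pv)
  expect_equal(dim(backv), c(12L, 16L, 9L))
  expect_equal(max(abs(unclass(backv) - unclass(v))), 0)
})

test_that("RGB images load as BT.709 luminance", {
  p <- withr::local_tempfile(fileext = ".png")
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 1, ] <- c(1, 1, 1)                 # white -> 255
  arr[1, 2, ] <- c(1, 0, 0)                 # red -> 0.2126 * 255
  arr[2, 1, ] <- c(0, 1, 0)                 # green
  png::writePNG(arr, p)
  g <- read_grid(p)
  expect_equal(g[1, 1], 255)
  expect_equal(g[1, 2], floor(0.2126 * 255 + 0.5))
  expect_equal(g[2, 1], floor(0.7152 * 255 + 0.5))
  expect_equal(g[2, 2], 0)
})

test_that("binarize thresholds grey grids with sensible defaults", {
  g <- grey_grid(matrix(128, 16, 16))
  expect_true(all(binarize(g) == 1L))
  expect_true(all(binarize(grey_grid(matrix(0, 16, 16))) == 0L))
  expect_true(all(binarize(g, threshold = 200) == 0L))
  rnd <- withr::with_seed(5, matrix(255 * stats::rbinom(256^2, 1, 0.5), 256, 256))
  frac <- mean(binarize(grey_grid(rnd)) == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 256^2))
})

test_that("CLI generates, analyzes, and is deterministic under a fixed seed", {
  td <- withr::local_tempdir()
  s_csv <- file.path(td, "s.csv")
  expect_equal(cli_main(c("gen1d", "--type", "wm", "--n", "1024", "--num", "3",
                          "--dim", "1.5", "--seed", "7", "-o", s_csv)), 0L)
  seqs <- read_sequences_csv(s_csv)
  expect_length(seqs, 3L)
  expect_true(all(lengths(seqs) == 1024L))

  r_csv <- file.path(td, "r.csv")
  expect_equal(cli_main(c("dim1d", "higuchi", "--kmax", "8", "--regmin", "1",
                          "--regmax", "8", s_csv, "-o", r_csv)), 0L)
  res <- utils::read.csv(r_csv)
  expect_equal(nrow(res), 3L)
  expect_true(all(c("Dim", "R2") %in% names(res)))
  expect_true(all(res$Dim > 1 & res$Dim < 2))

  # surrogate columns: per-surrogate values plus mean and SD
  expect_equal(cli_main(c("dim1d", "higuchi", "--surrogates", "shuffle",
                          "--n-surr", "5", "--seed", "3", s_csv, "-o", r_csv)), 0L)
  res2 <- utils::read.csv(r_csv, check.names = FALSE)
  expect_true(all(c(paste0("Surr-", 1:5), "Surr-Mean", "Surr-SD") %in% names(res2)))
  expect_equal(res2[["Surr-Mean"]],
               rowMeans(as.matrix(res2[paste0("Surr-", 1:5)])))

  # identical seeds give byte-identical outputs
  s2 <- file.path(td, "s2.csv")
  cli_main(c("gen1d", "--type", "wm", "--n", "256", "--num", "2",
             "--dim", "1.5", "--seed", "9", "-o", s_csv))
  cli_main(c("gen1d", "--type", "wm", "--n", "256", "--num", "2",
             "--dim", "1.5", "--seed", "9", "-o", s2))
  expect_identical(readLines(s_csv), readLines(s2))

  expect_equal(cli_main("no-such-command"), 2L)
  expect_equal(cli_main(c("dim1d", "higuchi", "missing.csv", "-o", r_csv)), 1L)
})

test_that("CLI covers grid, entropy and complexity paths", {
  td <- withr::local_tempdir()
  img <- file.path(td, "img.tif")
  expect_equal(cli_main(c("gen2d", "--type", "surface_fft", "--width", "128",
                          "--height", "128", "--dim", "2.5", "--seed", "4",
                          "-o", img)), 0L)
  out <- file.path(td, "out.csv")
  expect_equal(cli_main(c("dim2d", "fft", img, "-o", out)), 0L)
  r <- utils::read.csv(out)
  expect_true(r$Dim > 2 && r$Dim < 3)

  expect_equal(cli_main(c("dim2d", "boxcount", img, "-o", out)), 0L)
  expect_equal(cli_main(c("noise", "--kind", "gaussian", "--level", "5",
                          "--seed", "2", img, "-o", file.path(td, "n.tif"))), 0L)
  expect_equal(cli_main(c("surrogate", "--method", "shuffle", "--seed", "2",
                          img, "-o", file.path(td, "surr.tif"))), 0L)

  s_csv <- file.path(td, "s.csv")
  cli_main(c("gen1d", "--type", "gaussian", "--n", "300", "--seed", "1",
             "-o", s_csv))
  expect_equal(cli_main(c("entropy", "sampen", "--m", "2", "--r", "0.2",
                          s_csv, "-o", out)), 0L)
  expect_true(utils::read.csv(out)$Entropy > 0)
  expect_equal(cli_main(c("complexity", "kolmogorov", s_csv, "-o", out)), 0L)
  kc <- utils::read.csv(out)
  expect_true(kc$compressed_bytes > 0 && kc$compressed_bytes < kc$original_bytes * 2)
})
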