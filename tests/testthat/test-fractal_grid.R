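# 2D/3D estimators: brute-force equality, analytic sets, symmetries.

test_that("box counting equals the brute-force tile count on random masks", {
  for (i in 1:3) {
    m01 <- random_mask(withr::with_seed(i, sample(33:64, 1)), p = 0.3, seed = i)
    got <- box_counting_dim(make_mask(m01), reg_min = 1,
                            reg_max = length(dyadic_scales(min(dim(m01)))))
    ref_counts <- bf_box_counts(m01, dyadic_scales(min(dim(m01))))
    expect_equal(got$series$measures, ref_counts, tolerance = 1e-10)
    ref_fit <- bf_ols_loglog(got$series$scales, ref_counts)
    expect_equal(got$dimension, -ref_fit$slope, tolerance = 1e-10)
  }
})

test_that("box counting is exact on full squares and IFS sets", {
  full <- make_mask(matrix(1, 128, 128))
  r <- box_counting_dim(full)
  expect_equal(r$series$measures, (128 / r$series$scales)^2, tolerance = 1e-12)
  expect_equal(r$dimension, 2, tolerance = 1e-12)
  expect_equal(r$fit$r_squared, 1, tolerance = 1e-12)

  carpet <- binarize(generate_image("ifs_menger", 81, 81, levels = 4)[[1]])
  rc <- box_counting_dim(carpet)
  expect_equal(rc$dimension, log(8) / log(3), tolerance = 1e-10)
  expect_equal(rc$fit$r_squared, 1, tolerance = 1e-10)

  cube <- binarize(generate_volume("ifs_menger_cube", 27, 27, 27, levels = 3))
  expect_equal(box_counting_dim(cube)$dimension, log(20) / log(3),
               tolerance = 1e-10)
  expect_error(box_counting_dim(make_mask(matrix(0, 32, 32))), "empty foreground")
})

test_that("raster estimators are invariant under rotation and mirroring", {
  m01 <- random_mask(64, p = 0.2, seed = 9)
  base_bc <- box_counting_dim(make_mask(m01))$dimension
  base_py <- pyramid_dim(make_mask(m01))$dimension
  base_la <- lacunarity(make_mask(m01), mode = "raster")$lacunarity
  for (tr in list(function(m) m[nrow(m):1, ],          # vertical mirror
                  function(m) m[, ncol(m):1],          # horizontal mirror
                  function(m) t(m))) {                 # transpose (reflection)
    m2 <- tr(m01)
    expect_equal(box_counting_dim(make_mask(m2))$dimension, base_bc,
                 tolerance = 1e-12)
    expect_equal(pyramid_dim(make_mask(m2))$dimension, base_py,
                 tolerance = 1e-12)
    expect_equal(lacunarity(make_mask(m2), mode = "raster")$lacunarity,
                 base_la, tolerance = 1e-12)
  }
})

test_that("pyramid pooling reproduces box counting behaviour", {
  full <- make_mask(matrix(1, 64, 64))
  r <- pyramid_dim(full)
  expect_equal(r$series$measures, (64 / r$series$scales)^2, tolerance = 1e-12)
  expect_equal(r$dimension, 2, tolerance = 1e-12)

  single <- matrix(0, 64, 64); single[17, 33] <- 1
  expect_equal(pyramid_dim(make_mask(single))$dimension, 0, tolerance = 1e-12)

  carpet <- binarize(generate_image("ifs_menger", 243, 243, levels = 5)[[1]])
  expect_equal(pyramid_dim(carpet)$dimension, log(8) / log(3), tolerance = 0.08)
})

test_that("Minkowski dilation dimension separates point, line and plane", {
  pt <- matrix(0, 64, 64); pt[32, 32] <- 1
  rp <- minkowski_dim(make_mask(pt))
  expect_equal(rp$series$measures, (2 * (1:8) + 1)^2, tolerance = 1e-12)
  expect_lt(rp$dimension, 0.5)

  ln <- matrix(0, 64, 64); ln[32, 5:60] <- 1
  expect_lt(abs(minkowski_dim(make_mask(ln))$dimension - 1), 0.15)

  sq <- make_mask(matrix(1, 128, 128))
  expect_lt(abs(minkowski_dim(sq)$dimension - 2), 0.05)
})

test_that("correlation dimension recovers uniform 2D and 1D measures", {
  sq <- make_mask(matrix(1, 64, 64))
  expect_equal(correlation_dim(sq, max_points = 2000, seed = 1)$dimension, 2,
               tolerance = 0.1 / 2)
  ln <- matrix(0, 512, 512); ln[10, ] <- 1
  expect_equal(correlation_dim(make_mask(ln), seed = 1)$dimension, 1,
               tolerance = 0.05 / 1)
  few <- matrix(0, 32, 32); few[5, 5] <- 1
  expect_error(correlation_dim(make_mask(few)), "too few")
})

test_that("generalized dimensions: uniform exactness and q-monotonicity", {
  gd <- generalized_dims(grey_grid(matrix(200, 64, 64)))
  for (r in gd) {
    expect_equal(r$dimension, 2, tolerance = 1e-12)
    expect_equal(r$fit$r_squared, 1, tolerance = 1e-12)
  }
  carpet <- generate_image("ifs_menger", 243, 243, levels = 5)[[1]]
  gdc <- generalized_dims(carpet, q_list = c(0, 1, 2))
  for (r in gdc) expect_equal(r$dimension, log(8) / log(3),
                              tolerance = 0.08 / (log(8) / log(3)))

  g <- grey_grid(matrix(withr::with_seed(2, stats::runif(64^2, 0, 255)), 64, 64))
  dq <- vapply(generalized_dims(g, q_list = c(-2, 0, 2, 4)),
               function(r) r$dimension, 0)
  expect_true(all(diff(dq) <= 1e-9))
  # D0 agrees with box counting of the support
  half <- random_mask(128, p = 0.5, seed = 4)
  d0 <- generalized_dims(grey_grid(half * 255), q_list = 0)[[1]]$dimension
  bc <- box_counting_dim(make_mask(half))$dimension
  expect_lt(abs(d0 - bc), 0.05)
  expect_error(generalized_dims(grey_grid(matrix(0, 32, 32))), "zero total mass")
})

test_that("spectral dimension recovers generated surfaces and volumes", {
  imgs <- generate_image("surface_fft", 256, 256, count = 2, dim = 2.5, seed = 12)
  df <- vapply(imgs, function(g) fft_dim_grid(g)$dimension, 0)
  expect_equal(mean(df), 2.5, tolerance = 0.15 / 2.5)

  v <- generate_volume("volume_fft", 64, 64, 64, dim = 3.5, seed = 13)
  expect_equal(fft_dim_grid(v)$dimension, 3.5, tolerance = 0.2 / 3.5)
  # dimension-exponent bookkeeping: D = (3E + 2 - beta) / 2
  r <- fft_dim_grid(imgs[[1]])
  expect_equal(r$dimension, (8 - r$beta) / 2, tolerance = 1e-12)
})

test_that("grid Higuchi is calibrated on the plane and tracks roughness", {
  ramp <- grey_grid(matrix(rep(seq(0, 255, length.out = 128), each = 128),
                           128, 128))
  expect_equal(higuchi_dim_grid(ramp)$dimension, 2, tolerance = 0.02 / 2)

  noise <- grey_grid(matrix(withr::with_seed(5, stats::runif(256^2, 0, 255)),
                            256, 256))
  expect_equal(higuchi_dim_grid(noise)$dimension, 3, tolerance = 0.15 / 3)

  surf <- generate_image("surface_fft", 256, 256, dim = 2.5, seed = 3)[[1]]
  expect_equal(higuchi_dim_grid(surf)$dimension, 2.5, tolerance = 0.2 / 2.5)
  expect_equal(higuchi_dim_grid(surf, variant = "profiles_1d")$dimension, 2.5,
               tolerance = 0.2 / 2.5)
  expect_error(higuchi_dim_grid(grey_grid(matrix(9, 64, 64))), "constant grid")
})

test_that("spectral and Higuchi surface dimensions agree across roughness", {
  for (dt in c(2.2, 2.5, 2.8)) {
    g <- generate_image("surface_fft", 256, 256, dim = dt, seed = 100 * dt)[[1]]
    expect_lt(abs(fft_dim_grid(g)$dimension - higuchi_dim_grid(g)$dimension),
              0.3)
  }
})

test_that("lacunarity equals brute force and detects gap structure", {
  m01 <- random_mask(48, p = 0.4, seed = 7)
  for (mode in c("raster", "gliding")) {
    got <- lacunarity(make_mask(m01), box_sizes = c(2, 5, 8), mode = mode)
    ref <- vapply(c(2, 5, 8), function(r) bf_lacunarity(m01, r, mode), 0)
    expect_equal(got$lacunarity, ref, tolerance = 1e-10)
  }
  ones <- make_mask(matrix(1, 64, 64))
  expect_equal(lacunarity(ones)$lacunarity, rep(1, 5), tolerance = 1e-12)

  bern <- random_mask(512, p = 0.5, seed = 8)
  lam1 <- lacunarity(make_mask(bern), box_sizes = 1)$lacunarity
  expect_equal(lam1, 2, tolerance = 0.02)

  carpet01 <- (unclass(generate_image("ifs_menger", 243, 243, levels = 5)[[1]]) > 0) * 1
  dens <- mean(carpet01)
  rand01 <- withr::with_seed(10, matrix(stats::rbinom(243^2, 1, dens), 243, 243))
  lam_c <- lacunarity(make_mask(carpet01), box_sizes = 9, mode = "gliding")$lacunarity
  lam_r <- lacunarity(make_mask(rand01), box_sizes = 9, mode = "gliding")$lacunarity
  expect_gt(lam_c, lam_r)
  expect_error(lacunarity(ones, box_sizes = 100), "box larger")
})

test_that("fragmentation index spans compact objects to isolated dust", {
  full <- make_mask(matrix(1, 256, 256))
  r <- ffi(full)
  expect_equal(r$dimension, 1, tolerance = 0.1 / 1)
  expect_equal(r$d_area, 2, tolerance = 1e-10)

  dust <- matrix(0, 128, 128); dust[seq(2, 127, 3), seq(2, 127, 3)] <- 1
  expect_equal(ffi(make_mask(dust))$dimension, 0, tolerance = 1e-12)

  carpet <- binarize(generate_image("ifs_menger", 81, 81, levels = 4)[[1]])
  fc <- ffi(carpet)$dimension
  expect_gt(fc, 0); expect_lt(fc, 1)
  single <- matrix(0, 32, 32); single[4, 4] <- 1
  expect_error(ffi(make_mask(single)), "single-pixel foreground")
})
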