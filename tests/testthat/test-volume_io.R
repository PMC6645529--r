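test_that("volume writers and readers round-trip 3D payloads", {
  set.seed(1)
  v <- volume_image(array(rnorm(16 * 12 * 10, 100, 30), c(16, 12, 10)), 10.4)
  td <- withr::local_tempdir()

  mhd <- file.path(td, "vol.mhd")
  write_volume(v, mhd)
  r <- read_volume(mhd)
  expect_identical(dim(r$data), dim(v$data))
  expect_identical(r$data, v$data)        # lossless
  expect_equal(r$voxel_size, 10.4)

  nii <- file.path(td, "vol.nii.gz")
  write_volume(v, nii)
  r2 <- read_volume(nii, 10.4)
  expect_equal(r2$data, v$data, tolerance = 1e-12, ignore_attr = TRUE)

  tif <- file.path(td, "vol.tif")
  write_volume(v, tif)
  r3 <- read_volume(tif, 10.4)
  expect_identical(dim(r3$data), dim(v$data))

  expect_error(read_volume(file.path(td, "vol.xyz")),
               class = "cortimap_format_error")
  expect_error(read_volume(file.path(td, "missing.mhd")),
               class = "cortimap_io_error")
  # 2D payload
  tif2d <- file.path(td, "flat.tif")
  tiff::writeTIFF(matrix(0.5, 8, 8), tif2d)
  expect_error(read_volume(tif2d, 10.4), class = "cortimap_dimensionality_error")
})

test_that("gaussian smoothing preserves constants, mean, and matches the kernel formula", {
  const <- volume_image(array(7, c(12, 12, 12)), 10)
  expect_equal(gaussian_smooth(const)$data, const$data, tolerance = 1e-12)

  # unit impulse: centre value = cube of the central weight of the
  # normalised 1D kernel exp(-x^2 / (2 sigma^2)), x in {-1, 0, 1}
  imp <- array(0, c(11, 11, 11)); imp[6, 6, 6] <- 1
  sm <- gaussian_smooth(volume_image(imp, 10), sigma = 0.65, kernel = 3)
  w <- exp(-(-1:1)^2 / (2 * 0.65^2)); w <- w / sum(w)
  expect_equal(sm$data[6, 6, 6], w[2]^3, tolerance = 1e-12)

  set.seed(2)
  v <- volume_image(array(runif(10^3, 0, 50), c(10, 10, 10)), 10)
  expect_equal(mean(gaussian_smooth(v)$data), mean(v$data), tolerance = 1e-6)

  expect_error(gaussian_smooth(v, kernel = 4), class = "cortimap_parameter_error")
  expect_identical(formals(gaussian_smooth)$sigma, 0.65)
})

test_that("otsu segmentation agrees with exhaustive search and is shift invariant", {
  # two-delta histogram
  set.seed(3)
  v <- volume_image(array(sample(c(10, 200), 8^3, TRUE), c(8, 8, 8)), 10)
  m <- otsu_segment(v)
  thr <- attr(m, "threshold")
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(m$data, array(v$data > 100, dim(v$data)))

  # brute-force oracle on assorted histograms
  gens <- list(
    function() rnorm(4000, 100, 20),
    function() c(rnorm(2000, 50, 10), rnorm(2000, 180, 25)),
    function() rexp(4000, 0.02),
    function() c(runif(3000, 0, 40), rnorm(1000, 150, 5)))
  for (i in seq_along(gens)) {
    set.seed(10 + i)
    x <- gens[[i]]()
    n <- 4000
    img <- volume_image(array(x[1:4000], c(20, 20, 10)), 10)
    got <- attr(otsu_segment(img), "threshold")
    expect_equal(got, otsu_bruteforce(img$data), tolerance = 1e-12)
  }

  # offset invariance of the mask
  img <- volume_image(array(c(rnorm(2000, 50, 10), rnorm(2000, 180, 25)),
                            c(20, 20, 10)), 10)
  shifted <- volume_image(img$data + 500, 10)
  expect_identical(otsu_segment(img)$data, otsu_segment(shifted)$data)

  expect_error(otsu_segment(volume_image(array(3, c(8, 8, 8)), 10)),
               class = "cortimap_degenerate_histogram_error")
})

test_that("voi selection keeps floor(fraction x length) proximal slices", {
  # foreground spanning slices 10..509 (0-based), length 500
  m <- array(FALSE, c(8, 8, 520))
  m[4:5, 4:5, 11:510] <- TRUE
  voi <- select_voi(binary_mask(m, 10.4), 0.80)
  zr <- attr(voi, "z_range")
  expect_identical(zr, c(10L, 410L))        # 400 slices retained, [10, 410)
  kept <- which(apply(voi$data, 3, any)) - 1L
  expect_identical(range(kept), c(10L, 409L))

  expect_identical(select_voi(binary_mask(m, 10.4), 1.0)$data, m)

  m2 <- array(FALSE, c(8, 8, 20)); m2[4, 4, 5:15] <- TRUE  # length 11
  voi2 <- select_voi(binary_mask(m2, 10.4), 0.5)
  expect_identical(sum(apply(voi2$data, 3, any)), 5L)       # floor(5.5)

  # subset property
  expect_true(all(voi$data <= m))
  expect_error(select_voi(binary_mask(m, 10.4), 0), class = "cortimap_parameter_error")
})

test_that("rigid registration recovers known transforms on analytic images", {
  fixed <- render_blobs()
  # integer shift (3, -2, 1): moving(x) = fixed(x + (3, -2, 1))
  moving <- render_blobs(rigid_transform(translation = c(3, -2, 1)))
  tf <- rigid_register(moving, fixed)
  expect_lt(max(abs(tf$translation - c(-3, 2, -1))), 0.2)
  expect_lt(max(abs(tf$rotation)), 0.2 * pi / 180 + 1e-3)

  # identity
  tf0 <- rigid_register(fixed, fixed)
  expect_lt(max(abs(tf0$translation)), 1e-3)
  expect_lt(max(abs(tf0$rotation)), 1e-4)

  # random small transforms: the registration recovers the inverse map
  set.seed(4)
  for (i in 1:2) {
    tt <- runif(3, -3, 3)
    rr <- runif(3, -3, 3) * pi / 180
    expect_tf <- invert_transform(rigid_transform(rr, tt))
    tf <- rigid_register(render_blobs(rigid_transform(rr, tt)), fixed)
    expect_lt(max(abs(tf$translation - expect_tf$translation)), 0.2)
    expect_lt(max(abs(tf$rotation - expect_tf$rotation)), 0.2 * pi / 180)
  }

  # content with no overlap: convergence warning with best-so-far transform
  a <- array(0, c(24, 24, 24)); b <- array(0, c(24, 24, 24))
  a[3:6, 3:6, 3:6] <- 100; b[19:22, 19:22, 19:22] <- 100
  expect_warning(
    rigid_register(volume_image(a, 10), volume_image(b, 10)),
    class = "cortimap_convergence_warning")
})

test_that("rigid transforms compose and invert to identity", {
  set.seed(5)
  for (i in 1:5) {
    tf <- rigid_transform(runif(3, -0.3, 0.3), runif(3, -4, 4))
    ti <- invert_transform(tf)
    R <- cortimap:::euler_matrix(tf$rotation) %*% cortimap:::euler_matrix(ti$rotation)
    expect_lt(max(abs(R - diag(3))), 1e-6)
    resid <- cortimap:::euler_matrix(tf$rotation) %*% ti$translation + tf$translation
    expect_lt(max(abs(resid)), 1e-6)
  }
})
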