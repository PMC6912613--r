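test_that("local variability map matches a direct neighborhood enumeration", {
  # constant image: variance of constants is zero everywhere
  f <- calibrated_frame(matrix(7, 32, 32), 1)
  expect_true(all(local_variability_map(f, 3) == 0))

  # one bright pixel on zero background: support is the Chebyshev ball
  m <- matrix(0, 21, 21); m[11, 11] <- 10
  v <- local_variability_map(calibrated_frame(m, 1), 2)
  pos <- which(v > 0, arr.ind = TRUE)
  expect_true(all(abs(pos[, 1] - 11) <= 2 & abs(pos[, 2] - 11) <= 2))
  expect_equal(nrow(pos), 25)

  # checkerboard, r = 1: interior value equals the enumerated 9-cell variance
  cb <- outer(1:12, 1:12, function(i, j) (i + j) %% 2)
  vcb <- local_variability_map(calibrated_frame(cb, 1), 1)
  expect_equal(vcb[6, 6], neighborhood_variance(cb, 6, 6, 1))

  # random image: implementation equals enumeration at random pixels,
  # including edge pixels under reflected padding
  set.seed(7)
  rm <- matrix(rnorm(30 * 25), 30, 25)
  vr <- local_variability_map(calibrated_frame(rm, 1), 3)
  for (k in 1:12) {
    i <- sample(30, 1); j <- sample(25, 1)
    expect_equal(vr[i, j], neighborhood_variance(rm, i, j, 3))
  }
  expect_equal(vr[1, 1], neighborhood_variance(rm, 1, 1, 3))
  expect_equal(vr[30, 25], neighborhood_variance(rm, 30, 25, 3))
})

test_that("variance window larger than the image is rejected", {
  f <- calibrated_frame(matrix(rnorm(25), 5, 5), 1)
  expect_error(local_variability_map(f, 3), "window larger")
})

test_that("segmentation recovers textured objects on quiet background", {
  # texture disk covering ~25% of the field, variance ratio 10
  sc <- make_culture_scene(areas_um2 = round(0.25 * 128^2), shape = "disk",
                           frame_shape = c(128, 128), variance_ratio = 10,
                           seed = 11)
  m <- segment_cells(sc$frame)
  expect_gte(iou(m, sc$truth_mask), 0.9)
  expect_gte(coverage_fraction(m), 0.23)
  expect_lte(coverage_fraction(m), 0.27)

  # constant image, fixed threshold: empty mask, confluency 0
  cf <- calibrated_frame(matrix(5, 64, 64), 1)
  expect_equal(coverage_fraction(segment_cells(cf, threshold = 0.1)), 0)

  # full-frame texture: uniformly covered
  ff <- render_textured_frame(binary_mask(matrix(1L, 128, 128), 1), seed = 3)
  expect_warning(mff <- segment_cells(ff), "unimodal")
  expect_gte(coverage_fraction(mff), 0.98)
})

test_that("segmentation is invariant to intensity offset and rescaling", {
  sc <- make_culture_scene(areas_um2 = c(900, 2500), shape = "rect",
                           frame_shape = c(96, 96), seed = 21)
  m0 <- segment_cells(sc$frame)
  shifted <- calibrated_frame(sc$frame$pixels + 100, 1)
  scaled <- calibrated_frame(sc$frame$pixels * 7.5, 1)
  expect_identical(segment_cells(shifted)$pixels, m0$pixels)
  expect_identical(segment_cells(scaled)$pixels, m0$pixels)
})

test_that("confluency series tracks coverage over a sequence", {
  # constant (empty) frames give all-zero confluency
  frames <- lapply(0:2, function(k)
    calibrated_frame(matrix(1, 48, 48), 1, time = k / 6))
  tl <- time_lapse(frames, 10)
  cs <- suppressWarnings(confluency_series(tl))
  expect_equal(cs$covered_fraction, c(0, 0, 0))
  expect_equal(cs$time, c(0, 1 / 6, 1 / 3))

  # growing synthetic colony: non-decreasing coverage
  radii <- c(12, 20, 28, 36)
  gframes <- lapply(seq_along(radii), function(k) {
    mk <- outer(1:128, 1:128, function(i, j)
      (i - 64)^2 + (j - 64)^2 <= radii[k]^2) * 1L
    render_textured_frame(binary_mask(mk, 1), seed = 100 + k,
                          time = (k - 1) / 6)$pixels |>
      calibrated_frame(1, time = (k - 1) / 6)
  })
  gs <- confluency_series(time_lapse(gframes, 10))
  expect_true(all(diff(gs$covered_fraction) > -0.01))
  expect_true(all(gs$covered_fraction >= 0 & gs$covered_fraction <= 1))

  # single frame: one-element series
  one <- confluency_series(time_lapse(gframes[1], 10))
  expect_equal(nrow(one), 1)
})

test_that("the arbitrary-range Otsu agrees with the reference implementation", {
  set.seed(5)
  x <- c(rnorm(4000, 0, 1), rnorm(2000, 6, 1.5))
  mine <- emtquant:::otsu_threshold(x)
  xr <- (x - min(x)) / diff(range(x))
  ref <- EBImage::otsu(EBImage::Image(matrix(xr, 60, 100)),
                       range = c(0, 1), levels = 256)
  ref <- ref * diff(range(x)) + min(x)
  # same 256-bin discretization: thresholds agree to within one bin width,
  # so the induced partitions differ on at most a sliver of the data
  expect_lt(abs(mine - ref), diff(range(x)) / 256 + 1e-12)
  expect_lt(abs(sum(x > mine) - sum(x > ref)) / length(x), 0.005)
})
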