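test_that("normalized perimeter matches closed forms", {
  # circle: P = 2 pi r, A = pi r^2
  r <- 37
  expect_equal(normalized_perimeter(pi * r^2, 2 * pi * r), 1)
  # square side s: P = 4 s, A = s^2
  s <- 12
  expect_equal(normalized_perimeter(s^2, 4 * s), 2 / sqrt(pi))
  expect_error(normalized_perimeter(0, 10), "> 0")
  expect_error(normalized_perimeter(10, -1), "> 0")
})

test_that("the contour estimator scores rasterized shapes near their truth", {
  d <- make_spheroid_shape("disk", r0_px = 100)
  rd <- spheroid_metrics(d$mask)$normalized_perimeter
  expect_gte(rd, 0.98); expect_lte(rd, 1.02)

  sq <- make_spheroid_shape("square", r0_px = 100)
  rs <- spheroid_metrics(sq$mask)$normalized_perimeter
  expect_lt(abs(rs - 2 / sqrt(pi)) / (2 / sqrt(pi)), 0.02)

  # 2:1 ellipse against the arc-length-integral oracle
  el <- make_spheroid_shape("ellipse", r0_px = 150, aspect = 2)
  truth <- ellipse_ratio_oracle(300, 150)
  re <- spheroid_metrics(el$mask)$normalized_perimeter
  expect_lt(abs(re - truth) / truth, 0.005)

  # star boundary against the dense-polygon truth
  st <- make_spheroid_shape("star", r0_px = 100, k = 5, amplitude = 0.3)
  rst <- spheroid_metrics(st$mask)$normalized_perimeter
  expect_lt(abs(rst - st$true_ratio) / st$true_ratio, 0.02)
})

test_that("extract_spheroid keeps the dominant aggregate", {
  # two textured blobs: the large one is reported
  mk <- matrix(0L, 160, 160)
  mk[30:129, 30:129] <- 1L   # 10^4 px
  mk[145:154, 145:154] <- 1L # 10^2 px satellite
  fr <- render_textured_frame(binary_mask(mk, 1), seed = 44)
  out <- extract_spheroid(fr)
  expect_equal(out$area, 100 * 100, tolerance = 0.1)

  # all-background (constant) frame: error
  blank <- calibrated_frame(matrix(3, 64, 64), 1)
  expect_error(suppressWarnings(extract_spheroid(blank)), "empty segmentation")
})

test_that("compactness series follows a star-to-disk morph", {
  amps <- c(0.3, 0.2, 0.1, 0)
  masks <- lapply(amps, function(a)
    make_spheroid_shape("star", r0_px = 80, k = 5, amplitude = a)$mask)
  truths <- vapply(amps, function(a)
    make_spheroid_shape("star", r0_px = 80, k = 5, amplitude = a)$true_ratio,
    numeric(1))
  cs <- compactness_series(masks, times = 0:3)
  expect_true(all(diff(cs$normalized_perimeter) < 0))
  expect_true(all(abs(cs$normalized_perimeter - truths) / truths < 0.02))

  # static disk movie: constant ratio at 1 within discretization
  dm <- make_spheroid_shape("disk", r0_px = 60)$mask
  cs2 <- compactness_series(list(dm, dm, dm), times = 0:2)
  expect_equal(length(unique(cs2$normalized_perimeter)), 1)
  expect_lt(abs(cs2$normalized_perimeter[1] - 1), 0.02)
})

test_that("the ratio is scale- and rotation-stable and minimal for disks", {
  # 2x upsampling changes the ratio by < 1% for objects >= 1000 px
  st <- make_spheroid_shape("star", r0_px = 40, k = 4, amplitude = 0.2)
  up <- st$mask$pixels[rep(seq_len(nrow(st$mask$pixels)), each = 2),
                       rep(seq_len(ncol(st$mask$pixels)), each = 2)]
  r1 <- spheroid_metrics(st$mask)$normalized_perimeter
  r2 <- spheroid_metrics(binary_mask(up, 0.5))$normalized_perimeter
  expect_lt(abs(r2 - r1) / r1, 0.01)

  # rotations of a rasterized square vary < 2%
  rots <- vapply(c(0, 0.3, 0.6, pi / 4), function(phi)
    spheroid_metrics(make_spheroid_shape("square", r0_px = 100,
                                         rotation = phi)$mask)$normalized_perimeter,
    numeric(1))
  expect_lt((max(rots) - min(rots)) / mean(rots), 0.02)

  # the disk attains the smallest ratio across the shape family
  ratios <- vapply(list(
    make_spheroid_shape("disk", r0_px = 80),
    make_spheroid_shape("ellipse", r0_px = 80, aspect = 2),
    make_spheroid_shape("star", r0_px = 80, k = 5, amplitude = 0.25),
    make_spheroid_shape("fourier", r0_px = 80, seed = 7)),
    function(s) spheroid_metrics(s$mask)$normalized_perimeter, numeric(1))
  expect_equal(which.min(ratios), 1L)
})

test_that("multi-spheroid series average with SEM via summarize_fields", {
  sers <- lapply(c(60, 80), function(r) {
    mk <- make_spheroid_shape("disk", r0_px = r)$mask
    compactness_series(list(mk, mk), times = 0:1)
  })
  avg <- summarize_fields(sers, "normalized_perimeter")
  expect_equal(avg$n, c(2, 2))
  expect_true(all(avg$sem >= 0))
  expect_equal(avg$mean[1],
               mean(c(sers[[1]]$normalized_perimeter[1],
                      sers[[2]]$normalized_perimeter[1])))
})
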