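test_that("identical frames give an exactly zero displacement field", {
  tl <- make_translating_timelapse(c(0, 0), frame_shape = c(96, 96), seed = 2)
  f <- tl$timelapse$frames[[1]]
  fld <- piv_pair(f, f)
  expect_true(all(fld$valid))
  expect_true(all(fld$d_row == 0 & fld$d_col == 0))
})

test_that("uniform translations are recovered to sub-pixel accuracy", {
  # whole-pixel, half-pixel and diagonal shifts; velocity in um/h at
  # 1 um/px and 10 min interval gives shift_px = v / 6
  cases <- list(c(3, 0), c(2.5, 0), c(0, 4), c(1.5, 2.5))
  for (k in seq_along(cases)) {
    sh <- cases[[k]]
    tl <- make_translating_timelapse(sh * 6, n_frames = 2, interval_min = 10,
                                     frame_shape = c(128, 128), seed = 30 + k)
    expect_equal(tl$shift_px_per_frame, sh)
    fld <- piv_pair(tl$timelapse$frames[[1]], tl$timelapse$frames[[2]])
    expect_gt(mean(fld$valid), 0.9)
    expect_lt(abs(mean(fld$d_row[fld$valid]) - sh[1]), 0.2)
    expect_lt(abs(mean(fld$d_col[fld$valid]) - sh[2]), 0.2)
  }
})

test_that("reversing the frame pair negates vectors, preserving magnitude", {
  tl <- make_translating_timelapse(c(12, 6), n_frames = 2, interval_min = 10,
                                   frame_shape = c(96, 96), seed = 8)
  a <- tl$timelapse$frames[[1]]; b <- tl$timelapse$frames[[2]]
  fwd <- piv_pair(a, b); rev <- piv_pair(b, a)
  ok <- fwd$valid & rev$valid
  expect_gt(mean(ok), 0.8)
  expect_equal(fwd$d_row[ok], -rev$d_row[ok], tolerance = 0.1)
  expect_equal(fwd$d_col[ok], -rev$d_col[ok], tolerance = 0.1)
})

test_that("displacements are invariant under global intensity scaling", {
  tl <- make_translating_timelapse(c(9, 0), n_frames = 2, interval_min = 10,
                                   frame_shape = c(96, 96), seed = 14)
  a <- tl$timelapse$frames[[1]]; b <- tl$timelapse$frames[[2]]
  f1 <- piv_pair(a, b)
  f2 <- piv_pair(calibrated_frame(a$pixels * 40 + 7, 1, time = a$time),
                 calibrated_frame(b$pixels * 40 + 7, 1, time = b$time))
  expect_equal(f1$d_row, f2$d_row, tolerance = 1e-8)
  expect_equal(f1$d_col, f2$d_col, tolerance = 1e-8)
})

test_that("structureless noise pairs are flagged invalid", {
  set.seed(99)
  a <- calibrated_frame(matrix(rnorm(96^2), 96), 1)
  b <- calibrated_frame(matrix(rnorm(96^2), 96), 1)
  fld <- piv_pair(a, b)
  expect_gt(mean(!fld$valid), 0.5)
})

test_that("piv_pair validates its inputs", {
  a <- calibrated_frame(matrix(rnorm(64^2), 64), 1)
  b <- calibrated_frame(matrix(rnorm(32^2), 32), 1)
  expect_error(piv_pair(a, b), "shape")
  expect_error(piv_pair(a, a, window = 8), ">= 16")
})

test_that("frame speed converts pixel displacements to um/h", {
  # all vectors (3, 4) px, 1 um/px, 10-min interval: |v| = 5 um / (1/6 h)
  fld <- structure(
    data.frame(row = c(20, 40), col = c(20, 40), d_row = c(3, 3),
               d_col = c(4, 4), peak_ratio = 2, valid = TRUE),
    pixel_size = 1, dt_h = 1 / 6, class = c("VelocityField", "data.frame"))
  expect_equal(frame_speed(fld), 30)

  fld$d_row <- 0; fld$d_col <- 0
  expect_equal(frame_speed(fld), 0)

  # masked averaging equals the brute-force mean over retained windows
  set.seed(4)
  n <- 12
  fld2 <- structure(
    data.frame(row = seq(10, 65, by = 5), col = 30, d_row = rnorm(n),
               d_col = rnorm(n), peak_ratio = 2, valid = TRUE),
    pixel_size = 2, dt_h = 0.5, class = c("VelocityField", "data.frame"))
  mk <- matrix(0L, 80, 80); mk[1:40, ] <- 1L
  msk <- binary_mask(mk, 2)
  keep <- fld2$row <= 40
  expect_equal(frame_speed(fld2, mask = msk),
               mean(sqrt(fld2$d_row[keep]^2 + fld2$d_col[keep]^2)) * 2 / 0.5)

  # all windows masked out: undefined, flagged
  mk0 <- binary_mask(matrix(0L, 80, 80), 2)
  expect_warning(sp <- frame_speed(fld2, mask = mk0), "no valid")
  expect_true(is.na(sp))
})

test_that("speed time series recovers a known drift and truncates at t_max", {
  tl <- make_translating_timelapse(c(10, 0), n_frames = 4, interval_min = 10,
                                   frame_shape = c(96, 96), seed = 6)
  ss <- speed_timeseries(list(tl$timelapse), use_mask = FALSE,
                         window = 32, overlap = 16, search_margin = 6)
  expect_equal(ss$n_fields, rep(1, 3))
  expect_equal(ss$sem, rep(0, 3))
  expect_true(all(abs(ss$mean_speed - 10) / 10 < 0.05))

  # frames at and beyond t_max are dropped before pairing
  fr <- lapply(c(98, 99, 101), function(t)
    calibrated_frame(tl$timelapse$frames[[1]]$pixels, 1, time = t))
  tl2 <- time_lapse(fr, 60)
  ss2 <- speed_timeseries(list(tl2), t_max = 100, use_mask = FALSE,
                          search_margin = 6)
  expect_equal(ss2$time, 98)   # only the (98, 99) pair survives
})
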