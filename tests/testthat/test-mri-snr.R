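test_that("ROI statistics follow the voxel-centre rule", {
  # constant image: mean c, sd 0
  sl <- image_slice(matrix(7, 64, 64), spacing = 1)
  st <- roi_stats(sl, roi_spec(c(0, 0), 10))
  expect_equal(st$mean, 7)
  expect_equal(st$sd, 0)
  # voxel count matches a direct enumeration of centres inside the circle
  ctrs <- expand.grid(x = (-31.5):31.5, y = (-31.5):31.5)
  expect_equal(st$n, sum(ctrs$x^2 + ctrs$y^2 < 100))

  # half c / half 2c split through the ROI centre: mean 1.5 c by symmetry
  g <- matrix(1, 64, 64)
  g[33:64, ] <- 2  # x > 0 half (rows index x)
  sl2 <- image_slice(g, spacing = 1)
  st2 <- roi_stats(sl2, roi_spec(c(0, 0), 10))
  expect_equal(st2$mean, 1.5)

  # ROI fully outside the grid is an error
  expect_error(roi_stats(sl, roi_spec(c(500, 0), 5)), "no voxel")
})

test_that("Method-4 SNR divides by the mean of four background means", {
  g <- matrix(2, 128, 128)
  # container of signal 100 at the centre
  sl0 <- image_slice(g, spacing = 1)
  mask <- outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, "+") < 19^2
  g[mask] <- 100
  sl <- image_slice(g, spacing = 1)
  bg <- default_background_rois(c(0, 0))
  expect_equal(snr_method4(sl, roi_spec(c(0, 0), 12), bg), 50)
  # background averaging rule: means 1,1,3,3 average to 2
  g2 <- matrix(0, 128, 128)
  xs <- (1:128 - 64.5)  # voxel centre coordinates
  grid_x <- matrix(xs, 128, 128)
  grid_y <- matrix(xs, 128, 128, byrow = TRUE)
  g2[(grid_x - 26)^2 + grid_y^2 < 9] <- 1
  g2[(grid_x + 26)^2 + grid_y^2 < 9] <- 1
  g2[grid_x^2 + (grid_y - 26)^2 < 9] <- 3
  g2[grid_x^2 + (grid_y + 26)^2 < 9] <- 3
  g2[mask] <- 100
  sl2 <- image_slice(g2, spacing = 1)
  expect_equal(snr_method4(sl2, roi_spec(c(0, 0), 12), bg), 50)
  # exactly four background ROIs are required
  expect_error(snr_method4(sl, roi_spec(c(0, 0), 12), bg[1:3]), "four")
  # zero background mean is a division error
  g3 <- matrix(0, 128, 128); g3[mask] <- 1
  expect_error(snr_method4(image_slice(g3, spacing = 1),
                           roi_spec(c(0, 0), 12), bg), "zero")
  # invariance under global intensity scaling
  sl_scaled <- image_slice(5 * g2, spacing = 1)
  expect_equal(snr_method4(sl_scaled, roi_spec(c(0, 0), 12), bg),
               snr_method4(sl2, roi_spec(c(0, 0), 12), bg))
})

test_that("multi-slice averaging and voxel-level statistics are consistent", {
  g <- matrix(2, 128, 128)
  mask <- outer((1:128 - 64.5)^2, (1:128 - 64.5)^2, "+") < 19^2
  g[mask] <- 100
  series <- lapply(1:5, function(l) image_slice(g, spacing = 1,
                                                slice_index = l))
  m <- multi_slice_snr(series, roi_spec(c(0, 0), 12),
                       default_background_rois(c(0, 0)), "s1")
  # identical slices: the average equals any slice's SNR
  expect_equal(m$snr_avg, m$per_slice$snr[1])
  expect_equal(nrow(m$per_slice), 5)
  # sigma_rel arithmetic: sd 1.47 on mean 100 -> 1.47 %
  expect_equal(100 * 1.47 / 100, 1.47)
  expect_equal(m$per_slice$sigma_rel,
               100 * m$per_slice$sd / m$per_slice$mean)
})

test_that("positional deltas pair by solution id and feed the RMS", {
  a <- c(s1 = 100, s2 = 50)
  expect_equal(unname(positional_deltas(a, a)), c(0, 0))
  b <- c(s2 = 51, s1 = 99)  # order must not matter
  expect_equal(positional_deltas(a, b), c(s1 = -1, s2 = 2))
  expect_error(positional_deltas(a, c(s1 = 99, s3 = 1)), "pair")
  # the packaged positional reference deltas reproduce the published RMS
  ref <- positional_reference_deltas()
  expect_equal(round(type_a_rms(ref$rotation_90), 2), 0.70)
  expect_equal(round(type_a_rms(ref$couch_edge), 2), 1.24)
})

test_that("SNR-to-hydrogen calibration matches the published fit quality", {
  ph <- phantom_solutions()
  fse <- calibrate_snr_to_h(ph$h_ratio, ph$snr_fse, ph$solution)
  gre <- calibrate_snr_to_h(ph$h_ratio, ph$snr_gre, ph$solution)
  expect_equal(round(fse$r_squared, 2), 1.00)
  expect_equal(round(gre$r_squared, 2), 0.96)
  # noiseless synthetic linear data recover the gain exactly
  h <- seq(0.3, 1, by = 0.1)
  cal <- calibrate_snr_to_h(h, 163 * h)
  expect_equal(coef(cal)[["slope"]], 163, tolerance = 1e-9)
  expect_equal(coef(cal)[["intercept"]], 0, tolerance = 1e-9)
  # inversion recovers the hydrogen ratio
  expect_equal(h_from_snr(cal, 163 * 0.65), 0.65, tolerance = 1e-9)
  expect_error(calibrate_snr_to_h(c(0.5, 0.6), c(1, 2)), "three")
  expect_error(calibrate_snr_to_h(c(0.5, 0.55, 0.6), c(1, 2, 3)),
               "degenerate")
})
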