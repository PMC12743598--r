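test_that("hexagonal layout is deterministic, non-overlapping and bounded", {
  lay1 <- phantom_layout(1)
  expect_equal(nrow(lay1$centers), 1)
  expect_equal(unlist(lay1$centers[1, ]), c(x = 0, y = 0))

  lay <- phantom_layout(10)
  expect_equal(nrow(lay$centers), 10)
  # reproducible across calls
  expect_identical(lay$centers, phantom_layout(10)$centers)
  # pairwise distances exceed the container diameter: no overlap
  d <- as.matrix(stats::dist(lay$centers))
  expect_gt(min(d[upper.tri(d)]), 2 * (lay$inner_radius + lay$wall))
  # every container (with its background ring) fits the field of view
  r <- sqrt(lay$centers$x^2 + lay$centers$y^2)
  expect_true(all(r + lay$inner_radius + lay$wall + 9 <= lay$fov / 2))
  expect_error(phantom_layout(0), "between")
  expect_error(phantom_layout(13), "between")
  # the first hexagonal ring maps onto itself under a 60 degree rotation
  lay7 <- phantom_layout(7)
  rot <- container_centers(lay7, rotation = 60)
  key <- function(df) sort(paste(round(df$x, 6), round(df$y, 6)))
  expect_equal(key(rot), key(lay7$centers))
})

test_that("rendering is seeded, bit-reproducible and noiseless-exact", {
  lay <- phantom_layout(3)
  tr <- ground_truth(c(1, 0.6, 0.3), gain = 163, noise = 1, seed = 42)
  s1 <- render_phantom_series(lay, tr, n_slices = 2)
  s2 <- render_phantom_series(lay, tr, n_slices = 2)
  expect_identical(s1[[1]]$grid, s2[[1]]$grid)
  expect_identical(s1[[2]]$grid, s2[[2]]$grid)
  # different seeds give different noise
  s3 <- render_phantom_series(lay, tr, n_slices = 1, seed = 43)
  expect_false(identical(s1[[1]]$grid, s3[[1]]$grid))

  # zero noise: piecewise-constant image, pipeline reproduces the
  # programmed ratio exactly through the intensity floor
  tr0 <- ground_truth(c(1, 0.6, 0.3), gain = 163, noise = 0, seed = 1)
  s0 <- render_phantom_series(lay, tr0, n_slices = 1, floor_eps = 1e-6)
  expect_setequal(unique(as.vector(s0[[1]]$grid)),
                  c(1e-6, 163 * c(1, 0.6, 0.3)))
  meas0 <- measure_phantom_series(s0, lay)
  expect_equal(vapply(meas0, function(m) m$snr_avg, numeric(1)),
               163 * c(1, 0.6, 0.3) / 1e-6, tolerance = 1e-12)
})

test_that("analytic Rician truth has the right limits and scaling", {
  tr <- ground_truth(c(0, 0.5, 1), gain = 100, noise = 2, seed = 1)
  # zero signal: the solution region is pure noise, expected SNR 1
  expect_equal(truth_snr(tr, 1), 1, tolerance = 1e-12)
  # high-signal limit: SNR approaches A / (sigma sqrt(pi/2)), linear in h
  snr_half <- truth_snr(tr, 2)
  snr_full <- truth_snr(tr, 3)
  expect_equal(snr_full / snr_half, 2, tolerance = 1e-3)
  expect_equal(snr_full, 100 / (2 * sqrt(pi / 2)), tolerance = 1e-3)
  # doubling the gain doubles the high-signal SNR
  tr2 <- ground_truth(c(0, 0.5, 1), gain = 200, noise = 2, seed = 1)
  expect_equal(truth_snr(tr2, 3) / truth_snr(tr, 3), 2, tolerance = 1e-3)
  # zero noise returns the infinite sentinel
  expect_identical(truth_snr(ground_truth(1, noise = 0), 1), Inf)
  # Monte Carlo check of the Rician moments at moderate SNR
  set.seed(8)
  draws <- sqrt((3 + stats::rnorm(2e5))^2 + stats::rnorm(2e5)^2)
  expect_equal(mean(draws), mrispr:::rician_mean(3, 1), tolerance = 0.01)
  expect_equal(stats::sd(draws), mrispr:::rician_sd(3, 1), tolerance = 0.01)
})

test_that("measured SNR tracks the analytic truth within sampling error", {
  lay <- phantom_layout(10)
  h <- c(1, 0.95, 0.9, 0.85, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3)
  tr <- ground_truth(h, gain = 163, noise = 1, seed = 7)
  series <- render_phantom_series(lay, tr, n_slices = 5)
  meas <- measure_phantom_series(series, lay)
  snr <- vapply(meas, function(m) m$snr_avg, numeric(1))
  truth <- vapply(seq_along(h), function(k) truth_snr(tr, k), numeric(1))
  # analytic standard error of a 5-slice Method-4 average: background
  # ROIs dominate (Rayleigh relative sd / sqrt(total background voxels))
  rois <- phantom_rois(lay)
  for (k in seq_along(h)) {
    n_bg <- sum(vapply(rois[[k]]$background, function(r)
      roi_stats(series[[1]], r)$n, numeric(1)))
    n_sig <- roi_stats(series[[1]], rois[[k]]$solution)$n
    rel_bg <- sqrt(4 / pi - 1)  # Rayleigh relative sd
    rel_sig <- mrispr:::rician_sd(163 * h[k], 1) /
      mrispr:::rician_mean(163 * h[k], 1)
    se <- truth[k] * sqrt(rel_bg^2 / n_bg + rel_sig^2 / n_sig) / sqrt(5)
    expect_lt(abs(snr[k] - truth[k]), 3 * se)
  }
  # linear recovery of the programmed hydrogen ratios
  cal <- calibrate_snr_to_h(h, snr)
  expect_gte(cal$r_squared, 0.99)
  # voxel-level relative sd converges to the analytic Rician value
  expect_equal(meas[[1]]$sigma_rel_rms, truth_sigma_rel(tr, 1),
               tolerance = 0.05)
})

test_that("positional RMS grows with injected jitter amplitude", {
  lay <- phantom_layout(6)
  h <- c(1, 0.9, 0.7, 0.6, 0.5, 0.3)
  # deterministic render (no noise) with a mild shading field, so that
  # positional deltas come from geometry alone
  tr <- ground_truth(h, gain = 163, noise = 0, shading = 0.05, seed = 1)
  primary <- measure_phantom_series(
    render_phantom_series(lay, tr, n_slices = 1), lay)
  rms_at <- function(amp) {
    shift <- c(amp, 0)
    series <- render_phantom_series(lay, tr, n_slices = 1,
                                    translation = shift)
    arb <- measure_phantom_series(series, lay, translation = shift)
    type_a_rms(positional_deltas(primary, arb))
  }
  rms <- vapply(c(5, 10, 20), rms_at, numeric(1))
  expect_true(all(diff(rms) > 0))
  expect_equal(rms_at(0), 0, tolerance = 1e-12)
})
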