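test_that("OLS agrees with a brute-force least-squares oracle", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(3:10, 1)
    x <- stats::rnorm(n)
    y <- 1.5 * x - 0.3 + stats::rnorm(n, 0, 0.2)
    m <- fit_line(x, y)
    oracle <- brute_force_line(x, y)
    expect_equal(m$intercept, oracle[1], tolerance = 1e-6)
    expect_equal(m$slope, oracle[2], tolerance = 1e-6)
    # refitting on the registered samples reproduces the line
    m2 <- fit_line(m$fit_samples$x, m$fit_samples$y)
    expect_identical(coef(m2), coef(m))
  }
  # two points: exact interpolation
  m <- fit_line(c(0, 2), c(1, 5))
  expect_equal(unname(coef(m)), c(1, 2))
  expect_equal(m$r_squared, 1)
  expect_error(fit_line(c(1, 1), c(0, 2)), "degenerate")
})

test_that("soft+bone calibration reproduces the published fit quality", {
  cal <- spr_calibration(t1_ref)
  main <- cal$models[[1]]
  expect_equal(round(main$r_squared, 2), 0.99)
  expect_equal(nrow(main$fit_samples), 33)  # inflated lung excluded
  # predictions are exact on the line and routing falls back to the joint fit
  h0 <- 0.9
  expect_equal(predict(cal, h0), main$slope * h0 + main$intercept)
  # the fitted line passes close to water (within the soft residual band)
  at_water <- predict(cal, 1.0)
  expect_lt(abs(at_water - 1.0), 3 * main$sigma)
})

test_that("relative differences are signed percents and adipose dominates", {
  cal <- spr_calibration(t1_ref)
  d <- residuals(cal)
  expect_equal(nrow(d), 34)
  # worked arithmetic: est 1.02 vs cal 1.00 -> +2 %
  m <- fit_line(c(0, 1), c(0.02, 1.02))  # line y = x + 0.02
  rec <- data.frame(name = "t", h_ratio = 1, spr = 1.00)
  expect_equal(relative_differences(m, rec)$delta, 2, tolerance = 1e-9)
  # a record on the line has zero delta
  rec_on <- data.frame(name = "on", h_ratio = 0.5, spr = 0.52)
  expect_equal(relative_differences(m, rec_on)$delta, 0, tolerance = 1e-9)
  # adipose is the largest-magnitude soft-tissue deviation
  soft <- d[d$group == "soft", ]
  expect_equal(soft$name[which.max(abs(soft$delta))], "Adipose")
  # excluding adipose shrinks the soft RMS below the all-soft value
  expect_lt(type_a_rms(soft$delta[soft$name != "Adipose"]),
            type_a_rms(soft$delta))
})

test_that("lung model anchors near the origin with a tight density law", {
  air <- alt_comp[alt_comp$name == "Air", ]
  inflated <- icru_comp[icru_comp$name == "Lung (inflated)", ]
  compressed <- alt_comp[alt_comp$name == "Lung (compressed)", ]
  lung <- build_lung_model(air, inflated, compressed,
                           spr_inflated = 0.258)
  expect_equal(round(lung$r_squared, 2), 1.00)
  # the air anchor sits near the origin
  expect_lt(lung$fit_samples$x[1], 0.01)
  expect_lt(lung$fit_samples$y[1], 0.01)
  # prediction at the inflated lung's hydrogen ratio
  expect_equal(predict(lung, 0.239, warn_extrapolation = FALSE), 0.258,
               tolerance = 0.002)
  # a density factor of 1 reproduces the unperturbed delta
  lung1 <- build_lung_model(air, inflated, compressed,
                            density_factors = 1, spr_inflated = 0.258)
  d0 <- relative_differences(lung1, data.frame(
    name = "inflated", h_ratio = lung1$fit_samples$x[2],
    spr = lung1$fit_samples$y[2]))$delta
  expect_equal(lung1$eval_samples$delta, d0, tolerance = 1e-9)
  # the +/- 2/10/20 percent density variants stay on the line:
  # RMS fit uncertainty at the published 0.05 percent scale
  expect_lt(lung$rms_fit_percent, 0.1)
  expect_gt(lung$rms_fit_percent, 0)
  expect_error(build_lung_model(air, inflated, compressed,
                                density_factors = c(1, -1)), "positive")
})

test_that("adipose lipid model has negative slope and near-perfect fit", {
  gr <- alt_comp[!is.na(alt_comp$lipid_pct), ]
  expect_equal(nrow(gr), 3)
  gr$spr <- spr_bethe(gr, energy = 100)
  m <- build_adipose_lipid_model(gr)
  expect_lt(coef(m)[["slope"]], 0)
  expect_equal(round(m$r_squared, 2), 1.00)
  # duplicated lipid fraction cannot define a line
  dup <- gr[c(1, 1), ]
  expect_error(build_adipose_lipid_model(dup), "degenerate")
})

test_that("routing sends lipid-rich, lung and ordinary queries to their models", {
  gr <- alt_comp[!is.na(alt_comp$lipid_pct), ]
  gr$spr <- spr_bethe(gr, energy = 100)
  adipose <- build_adipose_lipid_model(gr)
  lung <- build_lung_model(alt_comp[alt_comp$name == "Air", ],
                           icru_comp[icru_comp$name == "Lung (inflated)", ],
                           alt_comp[alt_comp$name == "Lung (compressed)", ])
  cal <- spr_calibration(t1_ref, lung = lung, adipose = adipose)

  # lipid 70 % -> adipose route
  expect_equal(route_and_predict(cal, 0.97, "soft", lipid_percent = 70),
               predict(adipose, 70, warn_extrapolation = FALSE))
  # lipid 10 % -> soft+bone route
  expect_equal(route_and_predict(cal, 0.98, "soft", lipid_percent = 10),
               predict(cal$models[[1]], 0.98, warn_extrapolation = FALSE))
  # lung_related -> lung route
  expect_equal(route_and_predict(cal, 0.239, "lung_related"),
               predict(lung, 0.239, warn_extrapolation = FALSE))
  # missing models raise configuration errors
  bare <- spr_calibration(t1_ref)
  expect_error(route_and_predict(bare, 0.2, "lung_related"), "lung")
  expect_error(route_and_predict(bare, 0.9, "soft", lipid_percent = 80),
               "adipose")
})

test_that("bone mineral fraction is inversely related to hydrogen", {
  bones <- icru_comp[icru_comp$group == "bone", ]
  expect_lt(bone_mineral_correlation(bones), -0.9)
})

test_that("model serialisation round-trips through JSON", {
  m <- fit_line(t1_ref$h_ratio, t1_ref$spr, t1_ref$name,
                domain_label = "all media", xlab = "h_ratio", ylab = "spr")
  path <- tempfile(fileext = ".json")
  write_spr_model(m, path)
  m2 <- read_spr_model(path)
  expect_equal(coef(m2), coef(m))
  expect_equal(m2$r_squared, m$r_squared)
  expect_equal(m2$fit_samples, m$fit_samples)
  expect_equal(predict(m2, 0.8, warn_extrapolation = FALSE),
               predict(m, 0.8, warn_extrapolation = FALSE))
  expect_error(read_spr_model(write_temp_csv(t1_ref)), "spr_line")
})

test_that("separate-group fitting and simulation behave sensibly", {
  cal <- spr_calibration(t1_ref, separate_groups = TRUE)
  expect_setequal(names(cal$models), c("soft", "bone"))
  # per-group fit reduces the soft RMS relative to the joint fit
  joint <- summary(spr_calibration(t1_ref))$group_stats
  sep <- summary(cal)$group_stats
  expect_lte(sep$rms_delta[sep$group == "soft"],
             joint$rms_delta[joint$group == "soft"])
  sims <- simulate(spr_calibration(t1_ref), nsim = 3, seed = 99)
  expect_equal(dim(sims), c(33, 3))
})
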