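test_that("fit_calibration recovers an exact line to machine precision", {
  x <- c(0, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.075, 0.1)
  fit <- fit_calibration(concentration_series(x, 145 * x + 7),
                         sigma_blank = 0.5)
  expect_equal(fit$slope, 145, tolerance = 1e-12)
  expect_equal(fit$intercept, 7, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$lod_mM, 3 * 0.5 / 145, tolerance = 1e-12)

  flat <- fit_calibration(concentration_series(x, rep(5, 8)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_true(is.na(flat$lod_mM))              # LOD undefined on a flat line
  expect_error(limit_of_detection(0, 0.5), "positive")
  expect_error(fit_calibration(concentration_series(c(0, 0.1), c(7, 21.5))),
               "3 distinct")
})

test_that("noisy calibration matches the closed-form OLS oracle", {
  set.seed(31)
  x <- c(0, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.075, 0.1)
  y <- 145 * x + 7 + rnorm(8, sd = 0.5)
  fit <- fit_calibration(concentration_series(x, y))
  o <- ols_oracle(x, y)
  expect_equal(fit$slope, o$slope, tolerance = 1e-10)
  expect_equal(fit$intercept, o$intercept, tolerance = 1e-10)
})

test_that("limit_of_detection follows the 3-sigma formula and scaling laws", {
  expect_equal(limit_of_detection(145, 0.5), 0.0103448, tolerance = 1e-5)
  expect_equal(round(1000 * limit_of_detection(145, 0.5)), 10)  # ~10 uM
  expect_equal(limit_of_detection(145, 0), 0)
  lod <- limit_of_detection(145, 0.5)
  expect_equal(limit_of_detection(145, 1.0), 2 * lod)
  expect_equal(limit_of_detection(290, 0.5), lod / 2)
  # invariant to common rescaling of rates and slope
  expect_equal(limit_of_detection(145 * 3.7, 0.5 * 3.7), lod)
})

test_that("iron_from_r1 inverts the standard curve, flagging negatives", {
  expect_equal(iron_from_r1(0.52), 0, ignore_attr = TRUE)
  expect_equal(iron_from_r1(1.81), 1.0, tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(fe <- iron_from_r1(0.40), "negative")
  expect_equal(as.numeric(fe), (0.40 - 0.52) / 1.29, tolerance = 1e-12)
  expect_true(attr(fe, "flagged"))
  # forward/inverse round trip
  for (c_mM in c(0, 0.05, 0.3, 1)) {
    r1 <- 0.52 + 1.29 * c_mM
    expect_equal(as.numeric(iron_from_r1(r1)), c_mM, tolerance = 1e-12)
  }
  expect_error(iron_from_r1(1, r1p = 0), "non-zero")
})

test_that("assemble_nmrd fills axes, sorts and averages duplicates", {
  pts <- data.frame(field_T = c(0.47, NA, 1, 0.47),
                    freq_MHz = c(NA, 20, NA, NA),
                    relaxivity = c(30, 28, 10, 32))
  prof <- assemble_nmrd(pts)
  expect_equal(prof$freq_MHz[prof$field_T == 0.47][1], 0.47 * 42.577)
  expect_equal(prof$freq_MHz[prof$field_T == 1], 42.577)
  expect_true(!is.unsorted(prof$field_T))
  # the two 0.47 T points average to 31
  expect_equal(prof$relaxivity[prof$field_T == 0.47][1], 31)
  # 20 MHz maps back to ~0.47 T
  expect_equal(prof$field_T[abs(prof$freq_MHz - 20) < 1e-9], 20 / 42.577,
               tolerance = 1e-12)
  expect_error(assemble_nmrd(data.frame(relaxivity = 1)), "field or")
})

test_that("field regimes and r2/r1 classes follow the printed definitions", {
  expect_equal(classify_field_regime(0.00007), "ULF")
  expect_equal(classify_field_regime(1.0), "IF")
  expect_equal(classify_field_regime(7), "HF")
  expect_equal(classify_field_regime(2), "other")
  expect_equal(classify_field_regime(c(0.05, 0.5, 1.5, 3.01)),
               c("ULF", "IF", "IF", "HF"))
  expect_error(classify_field_regime(0), "positive")

  expect_equal(classify_contrast_agent(10, 40)$class, "T1-dominant")
  expect_equal(classify_contrast_agent(10, 40)$ratio, 4)
  expect_equal(classify_contrast_agent(1, 12)$class, "T2-dominant")
  expect_equal(classify_contrast_agent(1, 7)$class, "intermediate")
  expect_error(classify_contrast_agent(0, 5), "positive")
})

test_that("end-to-end phantom pipeline recovers generating slope/intercept", {
  for (sb in list(c(10, 20), c(145, 7), c(700, 2))) {
    sim <- generate_phantom(small_phantom_spec(relaxivity_slope = sb[1],
                                               background_rate = sb[2]))
    fits <- fit_volume(sim$volume, bi = FALSE)
    labs <- sim$truth$labels
    r2vox <- 1000 / fits$mono_t2
    r2_tube <- vapply(seq_len(nrow(sim$truth$tubes)),
                      function(k) mean(r2vox[labs == k]), numeric(1))
    cal <- fit_calibration(
      concentration_series(sim$truth$tubes$fe_mM, r2_tube))
    expect_equal(cal$slope, sb[1], tolerance = 1e-4)
    expect_equal(cal$intercept, sb[2], tolerance = 1e-4)
    # background subtraction moves the intercept to zero, not the slope
    bg <- mean(r2vox[labs == 0])
    cal2 <- fit_calibration(concentration_series(
      sim$truth$tubes$fe_mM, subtract_background(r2_tube, bg)))
    expect_equal(cal2$slope, sb[1], tolerance = 1e-4)
    expect_equal(cal2$intercept, 0, tolerance = 1e-4)
  }
})
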