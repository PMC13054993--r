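test_that("information criteria match the printed formulas", {
  ic <- information_criteria(1, 40, 2)
  expect_equal(ic$aic, 4)                      # 40 ln 1 + 2*2
  expect_equal(ic$bic, 2 * log(40))            # ~7.3778
  ic2 <- information_criteria(exp(1), 10, 4)
  expect_equal(ic2$aic, 18)                    # 10 + 8
  expect_equal(ic2$bic, 10 + 4 * log(10))
  # rss = 0 is floored, not -Inf
  ic0 <- information_criteria(0, 40, 2, signal_max = 100)
  expect_true(is.finite(ic0$aic) && is.finite(ic0$bic))
  expect_equal(ic0$aic, 40 * log(1e-12 * 40 * 100^2) + 4)
  expect_error(information_criteria(-1, 40, 2), "rss")
})

test_that("at equal rss the deltas are pure parsimony penalties", {
  for (n in c(10, 40, 64)) {
    icm <- information_criteria(5, n, 2)
    icb <- information_criteria(5, n, 4)
    expect_equal(icm$aic - icb$aic, -2 * (4 - 2))
    expect_equal(icm$bic - icb$bic, -(4 - 2) * log(n))
  }
})

test_that("deltas increase monotonically as the bi fit improves", {
  n <- 40
  rss_mono <- 50
  rss_bi <- seq(40, 1, by = -1)
  daic <- vapply(rss_bi, function(r)
    information_criteria(rss_mono, n, 2)$aic -
      information_criteria(r, n, 4)$aic, numeric(1))
  dbic <- vapply(rss_bi, function(r)
    information_criteria(rss_mono, n, 2)$bic -
      information_criteria(r, n, 4)$bic, numeric(1))
  expect_true(all(diff(daic) > 0))
  expect_true(all(diff(dbic) > 0))
})

test_that("select_model applies the OR/AND rules and the mono guard", {
  # craft curves whose fits land in the delta regimes of interest
  sch <- msme_schedule()
  y_bi <- bi_decay(bi_params(50, 50, 20, 200), sch$times)
  fm <- fit_mono(decay_curve(sch, y_bi))
  fb <- fit_bi(decay_curve(sch, y_bi))
  s_and <- select_model(fm, fb, rule = "AND")
  s_or <- select_model(fm, fb, rule = "OR")
  expect_gt(s_and$delta_aic, 10)
  expect_gt(s_and$delta_bic, 10)
  expect_equal(s_and$chosen, "bi")
  expect_equal(s_or$chosen, "bi")
  expect_equal(s_and$delta_aic, s_and$aic_mono - s_and$aic_bi)
  expect_equal(s_and$delta_bic, s_and$bic_mono - s_and$bic_bi)

  # noiseless mono curve: both rss at the floor, delta_aic = -4 -> mono
  y_m <- mono_decay(mono_params(100, 50), sch$times)
  fm2 <- fit_mono(decay_curve(sch, y_m))
  fb2 <- fit_bi(decay_curve(sch, y_m))
  s2 <- select_model(fm2, fb2)
  expect_equal(s2$delta_aic, -4, tolerance = 1e-8)
  expect_equal(s2$chosen, "mono")

  # OR vs AND disagreement region: threshold between the two deltas.
  # delta_bic < delta_aic always (n=40: ln n > 2), so pick threshold between.
  thr <- (s_and$delta_bic + s_and$delta_aic) / 2
  expect_equal(select_model(fm, fb, rule = "OR", threshold = thr)$chosen, "bi")
  expect_equal(select_model(fm, fb, rule = "AND", threshold = thr)$chosen,
               "mono")

  # effectively-mono bi fits are never selected
  sb <- select_model(fm2, fb2, rule = "OR", threshold = -100)
  expect_equal(sb$chosen, "mono")

  f_other <- fit_mono(decay_curve(msme_schedule(n_echoes = 20),
                                  mono_decay(mono_params(10, 30),
                                             msme_schedule(n_echoes = 20)$times)))
  expect_error(select_model(f_other, fb), "n mismatch")
})

test_that("build_maps reproduces ground truth on a noiseless injection volume", {
  sim <- generate_injection_volume(injection_spec())
  res <- fit_maps(sim$volume)
  maps <- res$maps
  truthbi <- sim$truth$labels == 2L
  expect_identical(dim(maps$binary_map), dim(sim$truth$labels))
  expect_equal(maps$voxel_size, sim$volume$voxel_size)
  ok <- !is.na(maps$binary_map)
  expect_true(all(ok))                           # uniform S0 -> full mask
  expect_true(all((maps$binary_map == 1) == truthbi))
  # fast/slow populated only where bi selected; mono map everywhere
  expect_true(all(is.na(maps$t2_fast_map[!truthbi])))
  expect_true(all(!is.na(maps$t2_fast_map[truthbi])))
  expect_equal(unname(maps$t2_fast_map[truthbi][1]), 20, tolerance = 1e-3)
  expect_equal(unname(maps$t2_slow_map[truthbi][1]), 200, tolerance = 1e-3)
  expect_true(all(!is.na(maps$t2_mono_map)))
})

test_that("pure-mono volumes give an all-zero binary map", {
  gs <- c(12, 12, 1)
  sim <- generate_injection_volume(injection_spec(
    grid_shape = gs,
    injection_region = disc_region(c(4, 6), 0.1, gs)[0, , drop = FALSE],
    contralateral_region = disc_region(c(9, 6), 2, gs)))
  maps <- fit_maps(sim$volume)$maps
  expect_true(all(maps$binary_map == 0, na.rm = TRUE))
})
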