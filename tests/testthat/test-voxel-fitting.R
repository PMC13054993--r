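test_that("fit_mono recovers noiseless parameters and reports degeneracy", {
  sch <- msme_schedule()
  y <- mono_decay(mono_params(100, 50), sch$times)
  f <- fit_mono(decay_curve(sch, y))
  expect_true(f$converged)
  expect_equal(f$params$s0, 100, tolerance = 1e-6)
  expect_equal(f$params$t, 50, tolerance = 1e-6)
  expect_lt(f$rss, 1e-12)
  expect_equal(f$n, 40)

  zero <- fit_mono(decay_curve(sch, rep(0, 40)))
  expect_false(zero$converged)
  expect_null(zero$params)
  bad <- fit_mono(decay_curve(sch, c(NaN, rep(1, 39))))
  expect_false(bad$converged)
})

test_that("fit_mono agrees with a dense grid-search oracle on noisy data", {
  set.seed(42)
  sch <- msme_schedule()
  y <- mono_decay(mono_params(100, 80), sch$times) + rnorm(40, sd = 1)
  f <- fit_mono(decay_curve(sch, y))
  g <- grid_search_mono(sch$times, y, s0_range = c(80, 120),
                        t2_range = c(40, 160))
  expect_equal(f$params$t, g$t2, tolerance = 0.05)
  expect_lte(abs(f$params$t - g$t2), g$step_t2)
  expect_lte(abs(f$params$s0 - g$s0), g$step_s0)
  expect_lte(f$rss, g$rss + 1e-9)
})

test_that("fit_bi round-trips noiseless bi curves and beats mono", {
  sch <- msme_schedule()
  y <- bi_decay(bi_params(50, 50, 20, 200), sch$times)
  fb <- fit_bi(decay_curve(sch, y))
  fm <- fit_mono(decay_curve(sch, y))
  expect_true(fb$converged)
  expect_equal(fb$params$a1, 50, tolerance = 1e-3)
  expect_equal(fb$params$a2, 50, tolerance = 1e-3)
  expect_equal(fb$params$t2_fast, 20, tolerance = 1e-3)
  expect_equal(fb$params$t2_slow, 200, tolerance = 1e-3)
  expect_lt(fb$rss, fm$rss)
  expect_false("effectively_mono" %in% fb$flags)
})

test_that("fit_bi flags collapse on mono input and matches the 4-D oracle", {
  sch <- msme_schedule()
  ym <- mono_decay(mono_params(100, 50), sch$times)
  fb <- fit_bi(decay_curve(sch, ym))
  expect_true("effectively_mono" %in% fb$flags)

  set.seed(7)
  y <- bi_decay(bi_params(50, 50, 20, 200), sch$times) + rnorm(40, sd = 1)
  f <- fit_bi(decay_curve(sch, y))
  o <- grid_search_bi(sch$times, y, a_range = c(30, 70),
                      tf_range = c(10, 40), ts_range = c(120, 300))
  got <- c(f$params$a1, f$params$a2, f$params$t2_fast, f$params$t2_slow)
  expect_equal(got, o$par, tolerance = 0.1)
  expect_lte(f$rss, o$rss * (1 + 1e-6) + 1e-9)
})

test_that("bi rss never exceeds mono rss (nesting) on varied curves", {
  set.seed(123)
  sch <- msme_schedule()
  for (i in 1:10) {
    truth_bi <- i %% 2 == 0
    y <- if (truth_bi)
      bi_decay(bi_params(runif(1, 20, 80), runif(1, 20, 80),
                         runif(1, 10, 40), runif(1, 100, 300)), sch$times)
    else mono_decay(mono_params(runif(1, 50, 150), runif(1, 20, 200)),
                    sch$times)
    y <- y + rnorm(40, sd = runif(1, 0, 2))
    fm <- fit_mono(decay_curve(sch, y))
    fb <- fit_bi(decay_curve(sch, y))
    expect_lte(fb$rss, fm$rss + 1e-6 * max(1, fm$rss))
  }
})

test_that("fits are invariant to the order of (time, signal) pairs", {
  set.seed(5)
  sch <- msme_schedule()
  y <- bi_decay(bi_params(60, 40, 25, 180), sch$times) + rnorm(40, sd = 0.5)
  perm <- sample(40)
  c1 <- decay_curve(sch, y)
  c2 <- decay_curve(sch$times[perm], y[perm])
  f1 <- fit_mono(c1); f2 <- fit_mono(c2)
  expect_identical(unclass(f1$params), unclass(f2$params))
  b1 <- fit_bi(c1); b2 <- fit_bi(c2)
  expect_identical(unclass(b1$params), unclass(b2$params))
})

test_that("fit_t1_ir handles signed, truncated and magnitude recovery data", {
  ti <- exp(seq(log(1), log(5000), length.out = 10))
  sch <- acq_schedule(ti, "IR")
  y <- ir_signal(mono_params(1, 100), ti)
  f <- fit_t1_ir(decay_curve(sch, y))
  expect_true(f$converged)
  expect_equal(f$params$t, 100, tolerance = 1e-4)
  expect_equal(f$params$s0, 1, tolerance = 1e-4)

  # sampling only after ~5 T1: recovery is flat, T1 ill-determined
  late <- seq(520, 2000, length.out = 8)
  ylate <- ir_signal(mono_params(1, 100), late)
  flate <- fit_t1_ir(decay_curve(acq_schedule(late, "IR"), ylate))
  expect_true(flate$converged)
  expect_true("ill_conditioned" %in% flate$flags)

  # magnitude data with imperfect inversion, beta free
  set.seed(9)
  ymag <- abs(ir_signal(mono_params(1, 120), ti, beta = 1.9))
  fmag <- fit_t1_ir(decay_curve(acq_schedule(ti, "IR"), ymag),
                    beta_free = TRUE, magnitude = TRUE)
  expect_equal(fmag$params$t, 120, tolerance = 0.01)
  expect_equal(fmag$beta, 1.9, tolerance = 0.05)

  expect_error(fit_t1_ir(decay_curve(msme_schedule(), rnorm(40))), "IR")
})

test_that("subtract_background is plain difference, negatives preserved", {
  expect_equal(subtract_background(21.5, 7.0), 14.5)
  expect_equal(subtract_background(7.0, 7.0), 0)
  expect_equal(subtract_background(6.9, 7.0), -0.1)
  expect_error(subtract_background(Inf, 7), "finite")
})

test_that("mask_volume thresholds on the first time point", {
  x <- array(1, dim = c(4, 4, 1, 3))
  expect_true(all(mask_volume(x, 0.05)))
  x2 <- x
  x2[1:2, , 1, ] <- 0
  m <- mask_volume(x2, 0.05)
  expect_false(any(m[1:2, , 1]))
  expect_true(all(m[3:4, , 1]))
  x3 <- array(runif(48), dim = c(4, 4, 1, 3))
  m3 <- mask_volume(x3, 1.0)
  expect_equal(sum(m3), sum(x3[, , , 1] == max(x3)))
})
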