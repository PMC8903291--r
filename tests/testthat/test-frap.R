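test_that("the four-step normalization matches hand arithmetic", {
  # pre frames: bleached 50, unbleached 80, background 5;
  # post frame: bleached 20, unbleached 40, background 5
  tr <- frap_trace(times_s = 0:3,
                   bleached = c(50, 50, 20, 20),
                   unbleached = c(80, 80, 40, 40),
                   background = c(5, 5, 5, 5), n_pre = 2)
  nm <- normalize_trace(tr)
  expect_equal(nm$pcv[3], 2)         # 80 / 40
  expect_equal(nm$cai[3], 40)        # 20 * 2
  expect_equal(nm$bcfi[3], 35)       # 40 - 5
  expect_equal(nm$fcv[3], 100 * 35 / 45, tolerance = 1e-12)  # 77.78
  expect_equal(round(nm$fcv[3], 2), 77.78)
})

test_that("constant traces normalize to a flat 100", {
  tr <- frap_trace(0:9, rep(60, 10), rep(90, 10), rep(10, 10), n_pre = 2)
  expect_equal(normalize_trace(tr)$fcv, rep(100, 10))
})

test_that("photobleach correction cancels shared per-frame decay exactly", {
  # drift-only trace: no recovery structure, no background, no noise
  sim <- gen_frap_trace(Fm = 0, t_half_s = 10, bleach_depth = 0,
                        drift_per_frame = 0.004, background_level = 0,
                        noise_sd = 0, seed = 1)
  nm <- normalize_trace(sim$trace)
  expect_equal(nm$fcv, rep(100, length(nm$fcv)), tolerance = 1e-9)

  # and the full recovery signal survives drift untouched
  sim2 <- gen_frap_trace(Fm = 0.82, t_half_s = 21.9, bleach_depth = 1,
                         drift_per_frame = 0.004, noise_sd = 0, seed = 1)
  nm2 <- normalize_trace(sim2$trace)
  expect_equal(nm2$fcv, sim2$truth$S, tolerance = 1e-6)
})

test_that("normalization rejects non-positive unbleached and degenerate baselines", {
  tr <- frap_trace(0:3, c(50, 50, 20, 20), c(80, 80, 0, 40),
                   c(5, 5, 5, 5), 2)
  expect_error(normalize_trace(tr), "strictly positive")
  tr2 <- frap_trace(0:3, c(1, 1, 2, 2), c(80, 80, 80, 80),
                    c(5, 5, 5, 5), 2)
  expect_error(normalize_trace(tr2), "normalization error")
})

test_that("fit_recovery recovers noiseless one-phase parameters exactly", {
  sim <- gen_frap_trace(Fm = 0.82, t_half_s = 21.9, bleach_depth = 1,
                        drift_per_frame = 0.002, noise_sd = 0, seed = 1)
  fit <- fit_recovery(normalize_trace(sim$trace))
  expect_true(fit$converged)
  expect_equal(fit$P, 82, tolerance = 1e-6)
  expect_equal(fit$t_half_s, 21.9, tolerance = 1e-6)
  expect_equal(fit$Fm, 0.82, tolerance = 1e-6)
})

test_that("a flat post-bleach trace yields a zero mobile fraction", {
  sim <- gen_frap_trace(Fm = 0, t_half_s = 10, bleach_depth = 0.7,
                        noise_sd = 0, seed = 1)
  fit <- fit_recovery(normalize_trace(sim$trace))
  expect_equal(fit$Fm, 0, tolerance = 1e-8)
})

test_that("fitting is invariant to uniform rescaling of the raw traces", {
  sim <- gen_frap_trace(Fm = 0.5, t_half_s = 18, noise_sd = 1.5, seed = 7)
  tr <- sim$trace
  fit1 <- fit_recovery(normalize_trace(tr))
  tr2 <- frap_trace(tr$times_s, tr$bleached * 37.5, tr$unbleached * 37.5,
                    tr$background * 37.5, tr$n_pre)
  fit2 <- fit_recovery(normalize_trace(tr2))
  expect_equal(fit1$Fm, fit2$Fm, tolerance = 1e-6)
  expect_equal(fit1$t_half_s, fit2$t_half_s, tolerance = 1e-6)
})

test_that("noisy single-trace recovery lands within a tight absolute band", {
  sim <- gen_frap_trace(Fm = 0.66, t_half_s = 21.9, noise_sd = 3, seed = 15)
  fit <- fit_recovery(normalize_trace(sim$trace))
  expect_lt(abs(fit$Fm - 0.66), 0.05)
})

test_that("fit_recovery never raises on pathological input", {
  # pure noise around a constant: K unidentifiable, must still return
  set.seed(2)
  fcv <- c(100, 100, rnorm(60, 50, 10))
  fit <- fit_recovery(fcv, times_s = seq_along(fcv) - 1, n_pre = 2L)
  expect_s3_class(fit, "frap_fit")
  expect_true(is.finite(fit$rss))
  expect_error(fit_recovery(fcv[1:8], times_s = 0:7, n_pre = 2L),
               "post-bleach")
})

test_that("extract_traces reproduces analytic traces from a rendered movie", {
  mv <- gen_frap_movie(Fm = 0.8, t_half_s = 10, n_post = 40, seed = 2)
  tr <- extract_traces(mv$stack, mv$rois, n_pre = 2)
  fit <- fit_recovery(normalize_trace(tr))
  expect_equal(fit$Fm, 0.8, tolerance = 0.01)
  expect_equal(fit$t_half_s, 10, tolerance = 0.1)
})

test_that("uniform frames give constant traces and ROI following tolerates drift", {
  flat <- ImageStack(array(7, c(3, 1, 1, 32, 32)), pixel_size_um = 0.1,
                     frame_interval_s = 1)
  rois <- list(bleached = roi_circle(c(10, 10), 3),
               unbleached = roi_circle(c(22, 22), 3),
               background = roi_circle(c(10, 22), 3))
  tr <- extract_traces(flat, rois, n_pre = 1)
  expect_equal(tr$bleached, rep(7, 3))
  expect_equal(tr$unbleached, rep(7, 3))
  expect_equal(tr$background, rep(7, 3))

  still <- gen_frap_movie(Fm = 0.8, t_half_s = 10, n_post = 40, seed = 2)
  drift <- gen_frap_movie(Fm = 0.8, t_half_s = 10, n_post = 40,
                          drift_px_per_frame = c(0.05, 0.05), seed = 2)
  f_still <- fit_recovery(normalize_trace(
    extract_traces(still$stack, still$rois, n_pre = 2)))
  f_drift <- fit_recovery(normalize_trace(
    extract_traces(drift$stack, drift$rois, n_pre = 2, follow = TRUE)))
  expect_lt(abs(f_drift$Fm - f_still$Fm) / f_still$Fm, 0.02)
})

test_that("frap_batch summarizes groups with correct SE semantics", {
  sims <- lapply(1:6, function(s)
    gen_frap_trace(Fm = 0.27, t_half_s = 7, noise_sd = 2, seed = s)$trace)
  out <- frap_batch(sims, groups = rep("kh2", 6))
  expect_equal(out$summary$n, 6)
  expect_lt(abs(out$summary$Fm_mean - 0.27), 0.03)
  expect_gt(out$summary$Fm_se, 0)

  single <- frap_batch(sims[1])
  expect_equal(single$summary$Fm_se, 0)
  expect_false(single$summary$se_defined)

  # identical traces have zero spread
  same <- frap_batch(rep(sims[1], 5))
  expect_equal(same$summary$Fm_se, 0, tolerance = 1e-12)
})
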