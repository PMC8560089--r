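test_that("generation is bit-identical under a fixed seed", {
  cfg <- synth_config(n_worms = 2, trials_per_worm = 3, seed = 17,
                      free_duration = 20)
  a <- generate_free_recording(cfg)
  b <- generate_free_recording(cfg)
  expect_identical(a$trials, b$trials)
  pa <- generate_prc_experiment(cfg)
  pb <- generate_prc_experiment(cfg)
  expect_identical(pa$trials, pb$trials)
  expect_identical(pa$truth, pb$truth)
  # different seeds give different data
  cfg2 <- synth_config(n_worms = 2, trials_per_worm = 3, seed = 18,
                       free_duration = 20)
  expect_false(identical(generate_free_recording(cfg2)$trials, a$trials))
})

test_that("free recordings inherit the slow-bend fast-straighten asymmetry", {
  cfg <- synth_config(n_worms = 2, seed = 30, free_duration = 30)
  fr <- generate_free_recording(cfg)
  for (tr in fr$trials) {
    cyc <- cycle_from_series(tr$t, tr$K)
    expect_gt(cyc$U, cyc$D)
  }
})

test_that("the perturbation experiment honors the protocol structure", {
  cfg <- synth_config(n_worms = 2, trials_per_worm = 10, seed = 12)
  ts <- generate_prc_experiment(cfg)
  man <- trial_manifest(ts)
  expect_equal(nrow(man), 20)
  expect_equal(as.integer(table(man$worm_id)), c(10L, 10L))
  # nominal 6 s spacing, jittered by at most one cycle
  for (w in unique(man$worm_id)) {
    sp <- diff(sort(man$pulse_start_s[man$worm_id == w]))
    expect_true(all(sp > 6 - 1.3 & sp < 6 + 1.3))
  }
  # onset phases cover the cycle
  expect_gt(diff(range(ts$truth$phi_true)), 4)
  # pulse windows have the configured duration
  expect_equal(man$pulse_end_s - man$pulse_start_s, rep(0.1, 20))
})

test_that("full censoring yields no analyzable trials, gracefully", {
  cfg <- synth_config(n_worms = 1, trials_per_worm = 3, censor_prob = 1,
                      seed = 2)
  ts <- generate_prc_experiment(cfg)
  expect_true(all(vapply(ts$trials, `[[`, logical(1), "censored")))
  pts <- analyze_trials(ts)
  expect_equal(nrow(pts), 0)
  expect_error(paralysis_lag_from_trials(ts), "no usable")
})

test_that("non-oscillatory generating parameters are rejected", {
  bad <- synth_config(params = model_params(P_th = 4, M0 = 3.5), seed = 1)
  expect_error(generate_free_recording(bad), "non-oscillatory")
  expect_error(generate_prc_experiment(bad), "non-oscillatory")
})
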