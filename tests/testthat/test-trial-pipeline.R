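# The per-trial phase-shift measurement, exercised on synthetic recordings
# with exact ground truth.

clean_cfg <- function(...) {
  synth_config(noise_sd = 0, period_jitter = 0, amplitude_jitter = 0,
               censor_prob = 0, ...)
}

test_that("an unperturbed synthetic trial yields a near-zero shift", {
  cfg <- clean_cfg(n_worms = 1, trials_per_worm = 2, seed = 21,
                   spec = inhibition_spec(depth = 0))
  ts <- generate_prc_experiment(cfg)
  for (tr in ts$trials) {
    res <- trial_phase_shift(tr)
    expect_lt(abs(res$dphi), 0.05)
  }
})

test_that("a known injected delay is recovered within 0.05 rad", {
  # build a trial from an unperturbed model cycle with its tail shifted
  tr <- fx_traj()
  ts <- seq(1, 16, by = 0.05)
  t_pulse <- 8.5
  delay <- 0.13 # seconds: post-pulse events happen `delay` later, so the
  # observed curvature there is the unperturbed one evaluated earlier
  tt <- ifelse(ts < t_pulse, ts, ts - delay)
  K <- approx(tr$t, tr$K, xout = tt)$y
  trial <- trial_record("w", "t", ts, K, pulse_start = t_pulse,
                        pulse_end = t_pulse + 0.1)
  res <- trial_phase_shift(trial)
  T0 <- attr(res, "T0")
  expect_equal(res$dphi, 2 * pi * delay / T0, tolerance = 0.05)
  # and an advance
  tt2 <- ifelse(ts < t_pulse, ts, ts + 0.1)
  trial2 <- trial_record("w", "t2", ts, approx(tr$t, tr$K, xout = tt2)$y,
                         pulse_start = t_pulse, pulse_end = t_pulse + 0.1)
  res2 <- trial_phase_shift(trial2)
  expect_equal(res2$dphi, -2 * pi * 0.1 / T0, tolerance = 0.05)
})

test_that("censored and pulse-free trials are rejected", {
  tr <- trial_record("w", "t", seq(0, 10, by = 0.05),
                     sin(seq(0, 10, by = 0.05)), censored = TRUE)
  expect_error(trial_phase_shift(tr), "censored")
  tr2 <- trial_record("w", "t", seq(0, 10, by = 0.05),
                      sin(seq(0, 10, by = 0.05)))
  expect_error(trial_phase_shift(tr2), "pulse")
})

test_that("pipeline round-trip: injected shifts recovered with small bias", {
  cfg <- synth_config(n_worms = 6, trials_per_worm = 10, seed = 5)
  ts <- generate_prc_experiment(cfg)
  pts <- analyze_trials(ts)
  expect_gt(nrow(pts), 25)
  m <- merge(data.frame(worm_id = pts$worm_id, trial_id = pts$trial_id,
                        dphi = pts$dphi),
             ts$truth, by = c("worm_id", "trial_id"))
  err <- (m$dphi - m$dphi_true + pi) %% (2 * pi) - pi
  expect_lt(abs(mean(err)), 0.02)
  expect_lt(sqrt(mean(err^2)), 0.1)
})

test_that("empirical paralysis lag matches the generating envelope's", {
  cfg <- clean_cfg(n_worms = 2, trials_per_worm = 8, seed = 9)
  ts <- generate_prc_experiment(cfg)
  lag <- paralysis_lag_from_trials(ts)
  expect_gt(lag$n_trials, 10)
  # generating envelope was calibrated for ~0.3 s after pulse end
  expect_equal(lag$lag, 0.3, tolerance = 0.1)
})

test_that("peak-delay calibration inverts the lag map", {
  p <- fitted_params()
  spec <- inhibition_spec()
  target <- paralysis_lag_from_trials(
    undulator:::model_pulse_trials(p, spec, n_phases = 8L))$lag
  pd <- calibrate_peak_delay(p, inhibition_spec(peak_delay = 0.3), target)
  expect_equal(pd, spec$peak_delay, tolerance = 0.03)
})
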