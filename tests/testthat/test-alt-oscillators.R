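sl_params <- function() fx("sl", function()
  alt_params("stuart_landau", lambda = 1, omega = 2 * pi,
             period = 1, amplitude = 2.1))
vdp_params <- function() fx("vdp", function()
  alt_params("vdp", mu = 5, period = 1, amplitude = 2.1))
ray_params <- function() fx("ray", function()
  alt_params("rayleigh", mu = 5, period = 1, amplitude = 2.1))

test_that("Stuart-Landau free running is sinusoidal with radius sqrt(lambda)", {
  sl <- sl_params()
  expect_equal(sl$T_sim, 1, tolerance = 1e-3)       # 2 pi / omega
  expect_equal(sl$A_sim, sqrt(1), tolerance = 1e-3) # on-cycle |z| = sqrt(lambda)
  tr <- simulate_alt(sl, duration = 25, thin = 10L)
  expect_lt(waveform_thd(tr), 0.01)
  # energy balance: |K| amplitude constant over many cycles
  ev <- attr(tr, "events")
  up <- ev$t[ev$sign == 1]
  amps <- vapply(head(up, -1), function(t0)
    max(abs(tr$K[tr$t >= t0 & tr$t < t0 + 1])), numeric(1))
  expect_lt(diff(range(amps[-(1:3)])) / mean(amps), 1e-3)
})

test_that("van der Pol is strongly nonsinusoidal with inverted asymmetry", {
  vp <- vdp_params()
  tr <- simulate_alt(vp, duration = 25, thin = 10L)
  expect_gt(waveform_thd(tr), 0.2)
  # inverted slow/fast asymmetry relative to the threshold-switch model:
  # |x| increases during less of the cycle than it decreases
  cyc <- cycle_from_series(tr$t, tr$K, smooth_window = 1)
  expect_lt(cyc$U, cyc$D)
  expect_gt(fx_cycle()$U, fx_cycle()$D)
})

test_that("the van der Pol variable is the derivative of the Rayleigh's", {
  # differentiating the Rayleigh equation and substituting x = sqrt(3) dy/dt
  # yields the van der Pol equation, so the steady-state waveform of
  # dx_rayleigh/dt matches x_vdp up to scaling: compare their peak-aligned
  # cycle-average waveforms after amplitude normalization
  vdp <- undulator:::sim_alt_cpp(0L, 5, 1, 2 * pi, 200, 5e-3, 2, 0, 0,
                                 undulator:::env_list(), 4L)
  ray <- undulator:::sim_alt_cpp(1L, 5, 1, 2 * pi, 200, 5e-3, 2, 0, 0,
                                 undulator:::env_list(), 4L)
  keep_v <- vdp$t > 60
  keep_r <- ray$t > 60
  dy <- undulator:::central_diff(ray$t[keep_r], ray$x[keep_r])
  cyc_r <- cycle_from_series(ray$t[keep_r], dy, smooth_window = 1)
  cyc_v <- cycle_from_series(vdp$t[keep_v], vdp$x[keep_v], smooth_window = 1)
  expect_equal(cyc_v$period, cyc_r$period, tolerance = 1e-3)
  a <- cyc_v$K / max(abs(cyc_v$K))
  b <- cyc_r$K / max(abs(cyc_r$K))
  expect_gt(cor(a, b), 0.99)
  expect_lt(max(abs(a - b)), 0.1)
})

test_that("alternative PRC shapes match their class", {
  spec <- inhibition_spec()
  # Stuart-Landau: radial contraction leaves the phase untouched
  prc_sl <- alt_prc(sl_params(), spec, n_phases = 16L)
  expect_lt(diff(range(prc_sl$dphi)), 0.02)
  # depth zero: flat for every kind
  for (ap in list(sl_params(), vdp_params())) {
    p0 <- alt_prc(ap, inhibition_spec(depth = 0), n_phases = 6L)
    expect_true(all(abs(p0$dphi) < 1e-6))
  }
  # van der Pol and Rayleigh: sawtooth (gradual one way, abrupt the other)
  for (ap in list(vdp_params(), ray_params())) {
    prc <- alt_prc(ap, spec, n_phases = 32L)
    d <- prc$dphi[c(2:32, 1)] - prc$dphi
    expect_gt(diff(range(prc$dphi)), 0.4)
    expect_gt(abs(min(d)), 2 * max(d))
    # 2 pi periodic and symmetric under half-period translation
    expect_equal(prc$dphi[1:16], prc$dphi[17:32], tolerance = 0.05)
  }
})

test_that("recovery rates: Stuart-Landau matches its Floquet exponent", {
  sl <- sl_params()
  spec <- inhibition_spec()
  # weak radial kick so the deviation stays in the linear regime
  tr <- simulate_alt(sl, duration = 25, spec = spec, onsets = 10, gain = 2,
                     thin = 10L)
  free <- simulate_alt(sl, duration = 25, thin = 10L)
  cyc <- cycle_from_series(free$t, free$K, smooth_window = 1)
  rate <- recovery_rate(tr, cyc, t_start = 10 + spec$peak_delay +
                          5 * spec$width)
  # radial linearization of r' = lambda r - r^3 about sqrt(lambda): -2 lambda,
  # in real time divided by the time scaling (here 1)
  expect_equal(as.numeric(rate), 2 * 1 / sl$time_scale, tolerance = 0.25)
  expect_error(recovery_rate(free, cyc, t_start = 10), "too small")
})

test_that("recovery rates are positive and comparable across models", {
  # displace each settled oscillator radially by the same factor and fit
  # the decay of the distance to the cycle. Both relaxation oscillators
  # contract strongly transverse to their cycles; the threshold model's
  # post-displacement recovery completes within a fraction of a cycle.
  vp <- vdp_params()
  freev <- simulate_alt(vp, duration = 30, thin = 10L)
  cycv <- cycle_from_series(freev$t, freev$K, smooth_window = 1)
  dispv <- simulate_alt(vp, duration = 20, thin = 10L, init = c(0.5, 0))
  rv <- recovery_rate(dispv, cycv, t_start = 0.02)
  expect_gt(as.numeric(rv), 1)

  tr <- fx_traj()
  n <- nrow(tr)
  dispt <- simulate_free_running(fitted_params(), duration = 15,
                                 initial = list(K = 0.6 * tr$K[n],
                                                Ma = 0.6 * tr$Ma[n],
                                                Mt = tr$Mt[n]), thin = 5L)
  rt <- recovery_rate(dispt, fx_cycle(), t_start = 0.02)
  expect_gt(as.numeric(rt), 1)
})

test_that("model comparison against a threshold-model target ranks it first", {
  rep <- fx("compare", function()
    model_comparison_report(fx_cycle(), fx_prc64(), fitted_params(),
                            inhibition_spec(), n_phases = 24L))
  expect_equal(rep$model[1], "threshold_switch")
  expect_true(all(rep$prc_mse[-1] > rep$prc_mse[1]))
  expect_true(all(rep$waveform_mse[rep$model == "threshold_switch"] <=
                    min(rep$waveform_mse[rep$model != "threshold_switch"])))
  # the advance-offset van der Pol PRC is the worst match to this target
  expect_equal(rep$model[which.max(rep$prc_mse)], "vdp")
  sl_mse <- rep$prc_mse[rep$model == "stuart_landau"]
  expect_gt(sl_mse, mean(fx_prc64()$dphi^2) * 0.5)
})
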