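test_that("parameter validation enforces the model's sanity constraints", {
  expect_error(model_params(tau_u = -1), "positive")
  expect_error(model_params(b = 0.3, tau_u = 0.26), "smaller than tau_u")
  expect_error(model_params(tau_u = NA), "finite")
  # P_th >= M0 is allowed here and flagged at simulation time
  p <- model_params(P_th = 4, M0 = 3.5)
  tr <- simulate_free_running(p, duration = 5)
  expect_false(attr(tr, "oscillatory"))
  expect_equal(nrow(switch_events(tr)), 0)
  # the fixed point is K = +/- M0
  expect_lt(abs(tail(tr$K, 1) - p$M0), 0.01)
})

test_that("closed-form period oracle matches its formula and flags degeneracy", {
  # frozen from T = 2 tau_u log((M0 + K_sw)/(M0 - K_sw)) evaluated by hand
  p <- model_params(tau_u = 0.26, tau_m = 1e-4, M0 = 3.0, b = 0, P_th = 2.33)
  expect_equal(period_tau_m_zero(p), 2 * 0.26 * log(5.33 / 0.67))
  expect_equal(period_tau_m_zero(p), 1.07843, tolerance = 1e-4)
  # P_th -> 0 gives T -> 0
  expect_lt(period_tau_m_zero(model_params(P_th = 1e-6, b = 0)), 1e-5)
  # switch curvature at or beyond M0: non-oscillatory, must error
  expect_error(period_tau_m_zero(model_params(P_th = 3.5, M0 = 3.5, b = 0)),
               "non-oscillatory")
})

test_that("simulated period matches the tau_m -> 0 closed form within 1%", {
  p <- model_params(tau_u = 0.26, tau_m = 1e-4, M0 = 3.0, b = 0, P_th = 2.33)
  tr <- simulate_free_running(p, duration = 12, thin = 5L)
  ev <- switch_events(tr)
  up <- ev$t[ev$sign == 1 & ev$t > 4]
  expect_gt(length(up), 4)
  T_sim <- mean(diff(up))
  expect_lt(abs(T_sim / period_tau_m_zero(p) - 1), 0.01)
  # with b > 0 the switch curvature changes and so does the period
  p2 <- model_params(tau_u = 0.26, tau_m = 1e-4, M0 = 3.0, b = 0.046,
                     P_th = 2.33)
  tr2 <- simulate_free_running(p2, duration = 12, thin = 5L)
  ev2 <- switch_events(tr2)
  T_sim2 <- mean(diff(ev2$t[ev2$sign == 1 & ev2$t > 4]))
  expect_lt(abs(T_sim2 / period_tau_m_zero(p2) - 1), 0.01)
})

test_that("free-running dynamics respect hysteresis and amplitude bounds", {
  # thresholds in the relaxation regime (K_sw a sizable fraction of M0);
  # near-sinusoidal low-threshold cycles lose the U > D asymmetry
  grid <- expand.grid(tau_u = c(0.15, 0.26, 0.5),
                      b = c(0, 0.046),
                      P_th = c(2.33, 3.0))
  for (i in seq_len(nrow(grid))) {
    p <- model_params(tau_u = grid$tau_u[i], b = grid$b[i],
                      P_th = grid$P_th[i])
    tr <- simulate_free_running(p, duration = 65 * p$tau_u + 5,
                                thin = 5L)
    ev <- switch_events(tr)
    expect_gt(nrow(ev), 4)
    # strict sign alternation of the target moment
    expect_true(all(diff(ev$sign) != 0))
    # amplitude bound: |K| < M0 always
    expect_lt(max(abs(tr$K)), p$M0)
    # asymmetry: bending (U) takes longer than straightening (D)
    lc <- extract_limit_cycle(tr)
    expect_gt(lc$U, lc$D)
    expect_lt(abs(lc$U + lc$D - 1), 0.05)
  }
})

test_that("amplitude approaches M0 as the threshold approaches M0", {
  amp_at <- function(pth) {
    tr <- simulate_free_running(model_params(P_th = pth, b = 0), duration = 40,
                                thin = 5L)
    extract_limit_cycle(tr)$amplitude
  }
  a1 <- amp_at(2.0); a2 <- amp_at(3.0); a3 <- amp_at(3.4)
  expect_true(a1 < a2 && a2 < a3)
  expect_gt(a3, 0.95 * 3.4)
})

test_that("halving the integration step changes the period by < 0.1%", {
  p <- fitted_params()
  T_at <- function(dt) {
    tr <- simulate_free_running(p, duration = 15, dt = dt, thin = 10L)
    ev <- switch_events(tr)
    mean(diff(ev$t[ev$sign == 1 & ev$t > 5]))
  }
  expect_lt(abs(T_at(5e-4) / T_at(2.5e-4) - 1), 1e-3)
})

test_that("switch events interpolate within steps and plateau near 0.5 s", {
  tr <- fx_traj()
  ev <- switch_events(tr)
  # events do not sit exactly on the storage grid (interpolated)
  dt_store <- attr(tr, "dt") * attr(tr, "thin")
  off <- (ev$t / dt_store) %% 1
  expect_gt(sd(off), 0.01)
  pl <- ev$plateau[ev$t > 6]
  expect_equal(mean(pl, na.rm = TRUE), 0.5, tolerance = 0.1)
})

test_that("limit cycle extraction reproduces an exactly periodic input", {
  lc <- fx_cycle()
  tr <- fx_traj()
  ev <- attr(tr, "events")
  up <- ev$t[ev$sign == 1]
  expect_equal(lc$period, mean(diff(up[up > 6])), tolerance = 1e-3)
  # the averaged waveform equals any single late cycle: sample one cycle
  # starting at a late ventral maximum
  late <- tr[tr$t > 20 & tr$t < 20 + 2.5 * lc$period, ]
  pk <- undulator:::dense_maxima(late$t, late$K)[1]
  tq <- pk + lc$phase / (2 * pi) * lc$period
  K1 <- approx(tr$t, tr$K, xout = tq)$y
  expect_lt(max(abs(K1 - lc$K)), 0.02)
})

test_that("extraction demands enough cycles", {
  p <- fitted_params()
  tr <- simulate_free_running(p, duration = 3, thin = 5L)
  expect_error(extract_limit_cycle(tr), "cycles")
})
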