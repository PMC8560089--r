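test_that("the suppression envelope has the documented shape", {
  spec <- inhibition_spec(depth = 0.7, peak_delay = 0.3, width = 0.05)
  t <- seq(-1, 2, by = 1e-3)
  eps <- inhibition_envelope(t, spec, onset = 0)
  expect_equal(max(eps), 0.7, tolerance = 1e-6)
  expect_equal(t[which.max(eps)], 0.3, tolerance = 2e-3)
  # truncated to exactly zero beyond five widths
  expect_true(all(eps[abs(t - 0.3) > 5 * 0.05] == 0))
  # zero depth disables the pulse entirely
  expect_true(all(inhibition_envelope(t, inhibition_spec(depth = 0)) == 0))
})

test_that("a depth-zero pulse leaves the trajectory untouched", {
  pair <- simulate_with_inhibition(fitted_params(),
                                   inhibition_spec(depth = 0), pi / 2,
                                   reference = fx_reference())
  expect_equal(pair$perturbed$K, pair$reference$K, tolerance = 1e-12)
  expect_equal(asymptotic_phase_shift(pair), 0, tolerance = 1e-9)
})

test_that("pre-pulse segments of a perturbed pair are identical", {
  pair <- simulate_with_inhibition(fitted_params(), inhibition_spec(), 0.4,
                                   reference = fx_reference())
  pre <- pair$perturbed$t < pair$pulse["onset"]
  expect_equal(pair$perturbed$K[pre], pair$reference$K[pre],
               tolerance = 1e-12)
  post <- pair$perturbed$t > pair$pulse["onset"] + 1
  expect_gt(max(abs(pair$perturbed$K[post] - pair$reference$K[post])), 0.01)
})

test_that("an artificial time shift maps to 2 pi dt / T0", {
  ref <- fx_reference()
  pair <- simulate_with_inhibition(fitted_params(),
                                   inhibition_spec(depth = 0), 0,
                                   reference = ref)
  for (dt_shift in c(0.08, -0.12, 0.4)) {
    fake <- pair
    ev <- attr(pair$perturbed, "events")
    ev$t <- ev$t + dt_shift
    attr(fake$perturbed, "events") <- ev
    expect_equal(asymptotic_phase_shift(fake),
                 2 * pi * dt_shift / pair$T0, tolerance = 1e-6)
  }
})

test_that("event-timing shift agrees with an isochron-map estimate", {
  # independent estimator: take the state at the end of the suppression
  # envelope and integrate it forward without any pulse; its late ventral
  # maxima define the asymptotic phase directly
  p <- fitted_params()
  spec <- inhibition_spec()
  ref <- fx_reference()
  for (phi in c(0.5, 2.5, 4.0)) {
    pair <- simulate_with_inhibition(p, spec, phi, reference = ref)
    dphi_events <- asymptotic_phase_shift(pair)
    t_free <- pair$pulse["onset"] + spec$peak_delay + 5 * spec$width
    i <- which.min(abs(pair$perturbed$t - t_free))
    st <- list(K = pair$perturbed$K[i], Ma = pair$perturbed$Ma[i],
               Mt = pair$perturbed$Mt[i])
    fwd <- simulate_free_running(p, duration = 12, initial = st, thin = 5L)
    ev_f <- attr(fwd, "events")
    up_f <- ev_f$t[ev_f$sign == 1] + pair$perturbed$t[i]
    ev_r <- attr(pair$reference, "events")
    up_r <- ev_r$t[ev_r$sign == 1]
    late_r <- up_r[up_r >= t_free + 6 * pair$T0]
    offs <- vapply(head(late_r, 4), function(tr_ev) {
      d <- up_f - tr_ev
      d <- d[which.min(abs(d))]
      (2 * pi * d / pair$T0 + pi) %% (2 * pi) - pi
    }, numeric(1))
    dphi_iso <- atan2(mean(sin(offs)), mean(cos(offs)))
    expect_equal(dphi_events, dphi_iso, tolerance = 0.02)
  }
})

test_that("early-phase pulses delay and post-jump pulses barely shift", {
  prc <- fx_prc64()
  early <- prc$dphi[prc$phi >= 0 & prc$phi <= pi / 6]
  expect_true(all(early > 0.1)) # clear delays
  # just after the downward transition the shift is small (near zero);
  # with multiplicative moment suppression it does not become clearly
  # negative (see the methods vignette)
  post <- prc$dphi[prc$phi > pi / 3 & prc$phi < pi / 2]
  expect_true(all(abs(post) < 0.35))
  expect_lt(min(prc$dphi), 0.2)
})

test_that("the model PRC is 2 pi periodic and symmetric under half a cycle", {
  prc <- fx_prc64()
  n <- nrow(prc)
  half <- n / 2
  # dorsoventral symmetry: dphi(phi + pi) = dphi(phi)
  expect_equal(prc$dphi[1:half], prc$dphi[(half + 1):n], tolerance = 0.02)
  # monotone teeth: between downward jumps the shift is non-decreasing
  d <- diff(prc$dphi)
  jumps <- which(d < -0.3)
  expect_length(jumps, 2L)
  rising <- d[-jumps]
  expect_true(all(rising > -0.05))
})

test_that("a short 0.055 s pulse preserves the sawtooth", {
  spec <- inhibition_spec(pulse_duration = 0.055)
  prc <- model_prc(fitted_params(), spec, n_phases = 32L,
                   reference = fx_reference())
  d <- diff(prc$dphi)
  expect_length(which(d < -0.3), 2L)
})

test_that("single-side PRCs are confined to the illuminated side's phases", {
  p <- fitted_params()
  ref <- fx_reference()
  sv <- inhibition_spec(side = "ventral")
  sd_ <- inhibition_spec(side = "dorsal")
  pv <- single_side_prc(p, sv, n_phases = 32L, reference = ref)
  pd <- single_side_prc(p, sd_, n_phases = 32L, reference = ref)
  # each side's response is near zero over at least a third of the cycle
  expect_gt(sum(abs(pv$dphi) < 0.05), 10)
  expect_gt(sum(abs(pd$dphi) < 0.05), 10)
  # the two teeth live on complementary phase ranges
  both_active <- sum(abs(pv$dphi) > 0.1 & abs(pd$dphi) > 0.1)
  expect_lt(both_active, 3)
  # dorsal response is weaker (depth_dorsal < depth)
  expect_lt(max(abs(pd$dphi)), max(abs(pv$dphi)))
  # depth zero: flat on either side
  p0 <- single_side_prc(p, inhibition_spec(depth = 0, side = "ventral"),
                        n_phases = 8L, reference = ref)
  expect_true(all(abs(p0$dphi) < 1e-9))
})

test_that("the model jump locator agrees with the PRC's largest step", {
  p <- fitted_params()
  spec <- inhibition_spec()
  tp <- prc_transition_phases(fx_prc64())
  J <- model_jump_phase(p, spec, reference = fx_reference())
  expect_lt(min(abs(J - tp)), 0.08)
})
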