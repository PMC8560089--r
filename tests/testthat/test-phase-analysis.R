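test_that("kymogram head averaging follows the 0.1-0.3 convention", {
  t <- seq(0, 5, by = 0.05)
  coords <- seq(0, 1, by = 0.02)
  # constant kymogram -> constant series
  kym <- matrix(1.7, length(t), length(coords))
  expect_equal(head_curvature_from_kymogram(kym, coords), rep(1.7, length(t)))
  # K = x * f(t) -> mean of x over [0.1, 0.3] = 0.2 times f(t)
  f <- sin(2 * pi * t)
  kym2 <- outer(f, coords)
  expect_equal(head_curvature_from_kymogram(kym2, coords), 0.2 * f,
               tolerance = 1e-6)
  # single column inside the range is returned unchanged
  expect_equal(head_curvature_from_kymogram(kym2[, coords == 0.2,
                                                 drop = FALSE], 0.2), 0.2 * f)
  expect_error(head_curvature_from_kymogram(kym, coords, range = c(0.1, 1.2)),
               "within")
})

test_that("phase is zero at ventral maxima and linear in between", {
  t <- seq(0, 10, by = 0.01)
  K <- 2 * cos(2 * pi * t / 1.3)
  phi <- phase_series(t, K)
  pk <- attr(phi, "peaks")
  expect_equal(diff(pk), rep(1.3, length(pk) - 1), tolerance = 1e-3)
  # phi = omega t mod 2pi for the cosine
  expected <- (2 * pi * t / 1.3) %% (2 * pi)
  inner <- t > 1.3 & t < 8.7
  err <- abs(phi[inner] - expected[inner])
  err <- pmin(err, 2 * pi - err)
  expect_lt(max(err), 0.05)
  # midpoint between consecutive maxima is phase pi
  mid <- (pk[2] + pk[3]) / 2
  expect_equal(phi[which.min(abs(t - mid))], pi, tolerance = 0.05)
  expect_error(phase_series(t[1:5], K[1:5]), "maxima")
})

test_that("smooth_prc is equivariant, honors flatness, and reports counts", {
  set.seed(1)
  pts <- prc_points(runif(60, 0, 2 * pi), rep(0, 60))
  sm <- smooth_prc(pts)
  expect_true(all(abs(sm$dphi[sm$ok]) < 1e-12))
  # adding a constant shifts the curve by exactly that constant
  pts2 <- pts; pts2$dphi <- pts2$dphi + 0.37
  sm2 <- smooth_prc(pts2)
  expect_equal(sm2$dphi, sm$dphi + 0.37, tolerance = 1e-12)
  # a constant curve is unchanged under any bin width
  sm3 <- smooth_prc(pts2, bin_width = 0.4 * pi)
  expect_true(all(abs(sm3$dphi[sm3$ok] - 0.37) < 1e-12))
  expect_equal(sum(sm$n), 60 * 64 * (0.16 * pi) / (2 * pi), tolerance = 0.2)
  expect_error(smooth_prc(prc_points(numeric(0), numeric(0))), "empty")
})

test_that("a noiseless sawtooth survives smoothing away from the jumps", {
  phi <- seq(0, 2 * pi, length.out = 201)[1:200]
  saw <- function(x) ((x - 1) %% pi) / pi - 0.5
  pts <- prc_points(phi, saw(phi))
  sm <- smooth_prc(pts)
  bw <- 0.16 * pi
  far <- sapply(sm$phi, function(g) {
    min(abs((g - c(1, 1 + pi) + pi) %% (2 * pi) - pi)) > bw
  })
  expect_lt(max(abs(sm$dphi[far] - saw(sm$phi[far]))), 0.02)
})

test_that("the 2-D PRC histogram conserves counts and separates modes", {
  set.seed(2)
  # bimodal cloud near a jump: delays ~1 before, advances ~-0.3 after
  phi <- c(runif(40, 0.8, 1.0), runif(40, 1.1, 1.3))
  dphi <- c(rnorm(40, 1, 0.05), rnorm(40, -0.3, 0.05))
  h <- prc_hist2d(prc_points(phi, dphi))
  expect_equal(sum(h$counts), 80)
  # no mass in the value gap between the modes
  gap <- h$dphi_breaks[-1] > 0 & h$dphi_breaks[-26] < 0.7
  expect_equal(sum(h$counts[, gap]), 0)
  h1 <- prc_hist2d(prc_points(1, 0.5))
  expect_equal(sum(h1$counts != 0), 1)
})

test_that("deviation metric hits its anchors", {
  cyc <- fx_cycle()
  expect_equal(deviation(0, 0, cyc), -1)
  # any state on the cycle: d = 0
  idx <- seq(1, length(cyc$K), by = 16)
  expect_lt(max(abs(deviation(cyc$K[idx], cyc$Kdot[idx], cyc))), 0.02)
  # doubling the radial distance gives d = +1
  expect_equal(deviation(2 * cyc$K[idx], 2 * cyc$Kdot[idx], cyc),
               rep(1, length(idx)), tolerance = 0.04)
  degen <- cyc; degen$sd_K <- 0
  expect_error(deviation(1, 1, degen), "degenerate")
})

test_that("tau_u estimators recover an exact exponential and the model", {
  # single exponential relaxation: the plateau regression is exact
  t <- seq(0, 1, by = 0.005)
  K <- 3.5 + (0.5 - 3.5) * exp(-t / 0.26)
  tau <- estimate_tau_u(t, K, Kdot = (3.5 - K) / 0.26, average = FALSE,
                        method = "plateau")
  expect_equal(as.numeric(tau), 0.26, tolerance = 1e-6)
  # dense model trajectory, two-line misfit method: within 5%
  tr <- fx_traj()
  tau2 <- estimate_tau_u(tr$t, tr$K, Kdot = tr$Kdot, average = FALSE)
  expect_equal(as.numeric(tau2), 0.26, tolerance = 0.05)
  # and its byproducts
  expect_equal(attr(tau2, "tau_m"), 0.1, tolerance = 0.1)
  expect_equal(attr(tau2, "M0"), 3.5, tolerance = 0.1)
})

test_that("tau_u recovery is stable across the physiological range", {
  # tau_u values clearly separated from tau_m = 0.1 s; the free-running
  # waveform cannot order the pair when the two time constants coincide
  for (tu in c(0.2, 0.26, 0.6)) {
    p <- model_params(tau_u = tu)
    tr <- simulate_free_running(p, duration = max(15, 40 * tu), thin = 5L)
    tau <- estimate_tau_u(tr$t, tr$K, Kdot = tr$Kdot, average = FALSE)
    expect_equal(as.numeric(tau), tu, tolerance = 0.05)
  }
})

test_that("moment reconstruction matches the simulated moment", {
  tr <- fx_traj()
  Ma <- estimate_moment_series(tr$K, tr$Kdot, 0.26)
  expect_lt(max(abs(Ma - tr$Ma)), 0.01 * 3.5)
  # at curvature extrema (Kdot = 0) the moment equals the curvature
  expect_equal(estimate_moment_series(1.9, 0, 0.26), 1.9)
  expect_error(estimate_moment_series(1:3, 1:2, 0.26), "equal length")
  # the reconstructed moment alternates between two plateaus
  late <- tr$t > 6
  expect_gt(mean(abs(Ma[late]) > 0.8 * 3.5), 0.5)
})

test_that("tau_m from the transition slope is exact for a step response", {
  t <- seq(0, 4 - 0.002, by = 0.002)
  Ma <- numeric(length(t))
  # alternate first-order steps between -2 and 2 every second
  lv <- c(2, -2)
  for (k in 0:3) {
    seg <- t >= k & t < k + 1
    from <- if (k == 0) -2 else lv[(k - 1) %% 2 + 1]
    to <- lv[k %% 2 + 1]
    Ma[seg] <- to + (from - to) * exp(-(t[seg] - k) / 0.1)
  }
  expect_equal(as.numeric(estimate_tau_m(t, Ma)), 0.1, tolerance = 0.02)
  # simulated trajectory with exact moment: within 10%
  tr <- fx_traj()
  keep <- tr$t > 6
  expect_equal(as.numeric(estimate_tau_m(tr$t[keep], tr$Ma[keep])), 0.1,
               tolerance = 0.1)
  expect_error(estimate_tau_m(t[1:100], Ma[1:100]), "plateaus|transitions")
})

test_that("cycle averaging reconstructs the waveform from sampled noisy data", {
  set.seed(7)
  tr <- fx_traj()
  ts <- seq(1, 29, by = 0.05)
  K20 <- approx(tr$t, tr$K, xout = ts)$y + rnorm(length(ts), 0, 0.1)
  cyc <- cycle_from_series(ts, K20)
  ref <- fx_cycle()
  expect_equal(cyc$period, ref$period, tolerance = 0.005)
  expect_equal(cyc$amplitude, ref$amplitude, tolerance = 0.05)
  expect_gt(cyc$U, cyc$D)
})

test_that("waveform-family fit recovers the generating parameters", {
  tr <- fx_traj()
  ts <- seq(1, 29, by = 0.05)
  K20 <- approx(tr$t, tr$K, xout = ts)$y
  tau <- estimate_tau_u(ts, K20, average = TRUE)
  expect_equal(as.numeric(tau), 0.26, tolerance = 0.08)
  expect_equal(attr(tau, "tau_m"), 0.1, tolerance = 0.1)
  expect_equal(attr(tau, "M0"), 3.5, tolerance = 0.1)
})

test_that("jump-phase change-point estimator finds a constructed jump", {
  set.seed(3)
  phi <- runif(150, 0, 2 * pi)
  J_true <- 1.2
  x <- (phi - J_true) %% (2 * pi)
  dphi <- ifelse(x < pi, 0.2 + 0.3 * x, -0.1 + 0.3 * (x - pi)) +
    rnorm(150, 0, 0.05)
  J <- estimate_prc_jumps(prc_points(phi, dphi))
  expect_equal(as.numeric(J), J_true, tolerance = 0.05)
})
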