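# van der Pol, Rayleigh and Stuart-Landau oscillators under the same
# perturbation/PRC interface as the threshold-switch model, for model
# comparison. Each system is integrated in its own scaled units and mapped
# onto the data's period and amplitude by linear time/amplitude rescaling.

ALT_KINDS <- c("vdp", "rayleigh", "stuart_landau")

#' Parameters for an alternative oscillator model
#'
#' * `vdp`: van der Pol, `x'' - mu (1 - x^2) x' + x = 0` — relaxation
#'   oscillator with displacement-dependent damping.
#' * `rayleigh`: `x'' - mu (1 - x'^2) x' + x = 0` — velocity-dependent
#'   damping; its solution is the time derivative of a matching van der Pol
#'   solution (up to scaling).
#' * `stuart_landau`: `z' = (lambda + i omega - |z|^2) z`, `x = Re z` — a
#'   harmonic (sinusoidal) limit cycle of radius `sqrt(lambda)`.
#'
#' On construction the free-running system is simulated once to measure its
#' natural period and amplitude in scaled units; simulations are then mapped
#' to the requested `period` and `amplitude` (defaults match the worm's head
#' oscillation at reference viscosity) by rescaling time and the state.
#'
#' @param kind one of `"vdp"`, `"rayleigh"`, `"stuart_landau"`.
#' @param mu nonlinearity strength (vdp/rayleigh); `mu ~ 5` gives a clearly
#'   relaxation-type cycle.
#' @param lambda,omega growth rate and angular frequency (stuart_landau).
#' @param period,amplitude target period (s) and curvature amplitude after
#'   rescaling.
#' @return an object of class `alt_params`.
#' @export
alt_params <- function(kind = ALT_KINDS, mu = 5, lambda = 1, omega = 2 * pi,
                       period = 1.0, amplitude = 2.1) {
  kind <- match.arg(kind)
  if (mu <= 0 || lambda <= 0 || omega <= 0)
    stop("mu, lambda and omega must be positive")
  if (period <= 0 || amplitude <= 0) stop("period and amplitude must be positive")
  obj <- structure(list(kind = kind, mu = mu, lambda = lambda, omega = omega,
                        period = period, amplitude = amplitude),
                   class = "alt_params")
  cal <- alt_calibrate(obj)
  obj$T_sim <- cal$T_sim
  obj$A_sim <- cal$A_sim
  obj$time_scale <- period / cal$T_sim
  obj$amp_scale <- amplitude / cal$A_sim
  obj
}

alt_kind_code <- function(kind) match(kind, ALT_KINDS) - 1L

# measure natural period and amplitude in scaled units
alt_calibrate <- function(p) {
  T_guess <- if (p$kind == "stuart_landau") 2 * pi / p$omega
             else max(2 * pi, (3 - 2 * log(2)) * p$mu)
  x0 <- if (p$kind == "stuart_landau") sqrt(p$lambda) else 2
  res <- sim_alt_cpp(alt_kind_code(p$kind), p$mu, p$lambda, p$omega,
                     duration = 20 * T_guess, dt = T_guess / 4000,
                     x0 = x0, y0 = 0, gain = 0,
                     env = env_list(), thin = 10L)
  up <- res$ev_t[res$ev_sign == 1]
  up <- up[up > 8 * T_guess]
  if (length(up) < 3) stop("alternative oscillator did not settle")
  keep <- res$t > 8 * T_guess
  list(T_sim = mean(diff(up)), A_sim = max(abs(res$x[keep])))
}

#' Simulate an alternative oscillator
#'
#' Integrates the chosen oscillator (RK4, fixed step) in scaled units and
#' returns the trajectory in real time and curvature units. A transient
#' muscle-inhibition pulse shares the Gaussian envelope of
#' [inhibition_spec()]: for van der Pol and Rayleigh the restoring drive is
#' suppressed multiplicatively (`-x` becomes `-x (1 - eps(t))`), the analog
#' of removing the muscle moment; for Stuart-Landau, whose rotation is not
#' driven by a restoring term, the pulse contracts the state radially toward
#' the origin at rate `gain * eps(t)`. Single-side specs gate the
#' suppression on the sign of the bending-like variable `x`.
#'
#' @param params an [alt_params()] object.
#' @param duration,dt simulated time and step (s, real units).
#' @param spec optional [inhibition_spec()].
#' @param onsets pulse onset times (s), if `spec` is given.
#' @param gain radial contraction strength for Stuart-Landau (1/s, real
#'   time); ignored by van der Pol and Rayleigh.
#' @param thin storage thinning.
#' @param init optional initial state `c(x, y)` in scaled units.
#' @return an `osc_traj`-like data frame (`t`, `K`, `Kdot`) with event
#'   attribute listing zero crossings of `K` (+1 upward) and attribute `T0`.
#' @export
simulate_alt <- function(params, duration = 30, dt = 5e-4,
                         spec = NULL, onsets = numeric(0), gain = 8,
                         thin = 1L, init = NULL) {
  stopifnot(inherits(params, "alt_params"))
  ts <- params$time_scale
  env <- env_list(spec, onsets)
  env$tc <- env$tc / ts
  env$width <- env$width / ts
  if (is.null(init))
    init <- c(if (params$kind == "stuart_landau") sqrt(params$lambda) else 2,
              0)
  res <- sim_alt_cpp(alt_kind_code(params$kind), params$mu, params$lambda,
                     params$omega, duration / ts, dt / ts,
                     x0 = init[1], y0 = init[2], gain = gain * ts,
                     env = env, thin = as.integer(thin))
  if (!res$ok) stop("integration produced non-finite state")
  t <- res$t * ts
  K <- res$x * params$amp_scale
  traj <- data.frame(t = t, K = K, Kdot = central_diff(t, K))
  ev <- data.frame(t = res$ev_t * ts, sign = as.integer(res$ev_sign))
  structure(traj, events = ev, dt = dt, thin = as.integer(thin),
            oscillatory = nrow(ev) >= 2L, params = params,
            class = c("osc_traj", "data.frame"))
}

#' Phase response curve of an alternative oscillator
#'
#' Mirrors [model_prc()]: pulses with the shared bell envelope are applied at
#' evenly spaced phases of the settled cycle (phase zero at the maximum of
#' `x`) and the asymptotic phase shift is measured from the timing of late
#' upward zero crossings.
#'
#' @inheritParams simulate_alt
#' @param n_phases number of onset phases.
#' @param skip_cycles,measure_cycles as in [asymptotic_phase_shift()].
#' @return a `prc_points` data frame.
#' @export
alt_prc <- function(params, spec, n_phases = 48L, dt = 5e-4, gain = 8,
                    skip_cycles = 5, measure_cycles = 5) {
  T0g <- params$period
  settle <- 8 * T0g
  dur <- settle + (3 + skip_cycles + measure_cycles + 2) * T0g
  ref <- simulate_alt(params, duration = dur, dt = dt, thin = 10L)
  ev <- attr(ref, "events")
  up <- ev$t[ev$sign == 1 & ev$t > settle / 2]
  T0 <- mean(diff(up))
  seg <- ref[ref$t >= settle & ref$t <= settle + 1.5 * T0, ]
  pk <- dense_maxima(seg$t, seg$K, min_height = -Inf)
  t0 <- pk[1]
  phis <- seq(0, 2 * pi, length.out = n_phases + 1L)[seq_len(n_phases)]
  dphi <- vapply(phis, function(phi) {
    t_on <- t0 + phi / (2 * pi) * T0
    pert <- simulate_alt(params, duration = dur, dt = dt, spec = spec,
                         onsets = t_on, gain = gain, thin = 10L)
    pair <- list(reference = ref, perturbed = pert,
                 pulse = c(onset = t_on, end = t_on + spec$pulse_duration),
                 T0 = T0, t0 = t0)
    asymptotic_phase_shift(pair, skip_cycles = skip_cycles,
                           measure_cycles = measure_cycles)
  }, numeric(1))
  prc_points(phis, dphi, T0 = T0)
}

# relative distance to the cycle: nearest-vertex distance in the
# sd-normalized plane over the mean cycle radius. Agrees with |deviation()|
# for near-circular cycles but stays well defined for strongly elongated
# ones (e.g. van der Pol), whose polar radius is multivalued.
cycle_distance <- function(K, Kdot, cycle) {
  if (cycle$sd_K <= 0 || cycle$sd_Kdot <= 0)
    stop("degenerate cycle: zero variance")
  x <- K / cycle$sd_K; y <- Kdot / cycle$sd_Kdot
  # upsample the cycle polyline: fast segments of relaxation cycles are
  # sparsely sampled on the phase grid, which would inflate the
  # nearest-vertex distance there
  ph <- cycle$phase
  fine <- seq(0, 2 * pi, length.out = 1025L)[1:1024]
  up <- function(v) approx(c(ph - 2 * pi, ph, ph + 2 * pi), rep(v, 3),
                           xout = fine)$y
  cx <- up(cycle$K) / cycle$sd_K
  cy <- up(cycle$Kdot) / cycle$sd_Kdot
  rbar <- mean(sqrt(cx^2 + cy^2))
  vapply(seq_along(x), function(i)
    sqrt(min((x[i] - cx)^2 + (y[i] - cy)^2)), numeric(1)) / rbar
}

#' Post-perturbation recovery rate toward the limit cycle
#'
#' Fits an exponential decay to the distance from the limit cycle after a
#' perturbation: the least-squares slope of `log d` versus time over the
#' window from `t_start` until the distance first falls below `d_floor`.
#' The distance is the nearest-point distance to the cycle in the
#' sd-normalized phase plane (relative to the mean cycle radius), which
#' matches `|deviation()|` for near-circular cycles but remains valid for
#' the strongly elongated van der Pol cycle. For the Stuart-Landau
#' oscillator the radial Floquet exponent gives an analytic decay rate
#' `2 * lambda` (scaled time) for comparison.
#'
#' @param traj perturbed trajectory (`osc_traj` with columns `K`, `Kdot`).
#' @param cycle the unperturbed `limit_cycle`.
#' @param t_start start of the fitting window (s), typically the end of the
#'   suppression envelope.
#' @param d_floor distance at which the fit window ends.
#' @return decay rate (1/s, positive = decaying), with the fitted window as
#'   attribute `window`.
#' @export
recovery_rate <- function(traj, cycle, t_start, d_floor = 0.02) {
  sel <- which(traj$t >= t_start)
  if (!length(sel)) stop("t_start beyond trajectory")
  d <- cycle_distance(traj$K[sel], traj$Kdot[sel], cycle)
  if (d[1] < 0.05) stop("deviation too small at t_start; no recovery to fit")
  stop_i <- which(d < d_floor)[1]
  if (is.na(stop_i)) stop_i <- length(d)
  if (stop_i < 5) stop("recovery window too short")
  tt <- traj$t[sel[1:stop_i]]
  fit <- lm(log(pmax(d[1:stop_i], 1e-12)) ~ tt)
  structure(-unname(coef(fit)[2]), window = range(tt))
}

#' Total harmonic distortion of a steady-state waveform
#'
#' Measures how far a settled oscillation deviates from a pure sinusoid: the
#' RMS amplitude of harmonics 2..`n_harm` relative to the fundamental, over an
#' integer number of cycles.
#'
#' @param traj an oscillatory trajectory with events.
#' @param n_cycles number of late full cycles analyzed.
#' @param n_harm highest harmonic included.
#' @return THD as a fraction (0 = pure sinusoid).
#' @export
waveform_thd <- function(traj, n_cycles = 10L, n_harm = 10L) {
  ev <- attr(traj, "events")
  up <- ev$t[ev$sign == 1]
  if (length(up) < n_cycles + 1) stop("not enough cycles for THD")
  t1 <- up[length(up) - n_cycles]
  t2 <- up[length(up)]
  sel <- traj$t >= t1 & traj$t < t2
  x <- traj$K[sel] - mean(traj$K[sel])
  sp <- abs(fft(x))[1:(floor(length(x) / 2))]
  fund <- n_cycles + 1L # bin of the fundamental for n_cycles periods
  h <- fund + (seq_len(n_harm - 1L)) * n_cycles
  h <- h[h <= length(sp)]
  sqrt(sum(sp[h]^2)) / sp[fund]
}

#' Compare oscillator models against target waveform and PRC
#'
#' Scales each alternative oscillator to the target's period and amplitude,
#' computes the mean squared error between its cycle-average waveform and the
#' target waveform (aligned at the curvature maximum, K^2 units) and between
#' its PRC and the target PRC (rad^2), and ranks the models. The
#' threshold-switch model is included via `params`.
#'
#' @param target_cycle target `limit_cycle`.
#' @param target_prc target PRC: a `prc_points` or `smoothed_prc` object.
#' @param params threshold-switch [model_params()].
#' @param spec [inhibition_spec()] applied to all models.
#' @param kinds alternative kinds to include.
#' @param n_phases phases per model PRC.
#' @param gain perturbation gain for the alternatives.
#' @param mu,lambda,omega alternative-model parameters.
#' @return a data frame with one row per model, columns `model`,
#'   `waveform_mse`, `prc_mse`, ranked by `prc_mse`.
#' @export
model_comparison_report <- function(target_cycle, target_prc, params, spec,
                                    kinds = ALT_KINDS, n_phases = 32L,
                                    gain = 8, mu = 5, lambda = 1,
                                    omega = 2 * pi) {
  tg_phi <- target_prc$phi
  tg_dphi <- target_prc$dphi
  grid <- target_cycle$phase

  wf_mse <- function(cyc) {
    Km <- approx(c(cyc$phase, 2 * pi), c(cyc$K, cyc$K[1]), xout = grid,
                 rule = 2)$y
    mean((Km - target_cycle$K)^2)
  }
  prc_mse <- function(prc) {
    Pm <- approx(c(prc$phi, 2 * pi), c(prc$dphi, prc$dphi[1]), xout = tg_phi,
                 rule = 2)$y
    mean((Pm - tg_dphi)^2, na.rm = TRUE)
  }

  rows <- list()
  thr_traj <- simulate_free_running(params, duration = 30, thin = 5L)
  thr_cyc <- extract_limit_cycle(thr_traj)
  thr_prc <- model_prc(params, spec, n_phases = n_phases)
  rows[["threshold_switch"]] <- c(wf_mse(thr_cyc), prc_mse(thr_prc))

  for (k in kinds) {
    ap <- alt_params(k, mu = mu, lambda = lambda, omega = omega,
                     period = target_cycle$period,
                     amplitude = target_cycle$amplitude)
    tr <- simulate_alt(ap, duration = 20 * ap$period, thin = 10L)
    cyc <- cycle_from_series(tr$t, tr$K, smooth_window = 1)
    prc <- alt_prc(ap, spec, n_phases = n_phases, gain = gain)
    rows[[k]] <- c(wf_mse(cyc), prc_mse(prc))
  }
  out <- data.frame(model = names(rows),
                    waveform_mse = vapply(rows, `[`, numeric(1), 1),
                    prc_mse = vapply(rows, `[`, numeric(1), 2),
                    row.names = NULL)
  out[order(out$prc_mse), ]
}
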