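# Reference machinery shared by the perturbation and PRC operations: settle
# the oscillator onto its limit cycle, measure the period T0 and locate a
# ventral-maximum time t0 (phase zero) from which pulse onsets are placed.

ref_settings <- function(params, dt) {
  T_guess <- tryCatch(period_tau_m_zero(params), error = function(e) NA_real_)
  if (!is.finite(T_guess)) T_guess <- 4 * params$tau_u + 8 * params$tau_m
  settle <- max(10 * params$tau_u, 4 * T_guess)
  list(T_guess = T_guess, settle = settle)
}

#' Build a settled reference trajectory for perturbation experiments
#'
#' Simulates the free-running oscillator long enough to settle, measures the
#' period `T0` from the switch events, and finds the time `t0` of a ventral
#' curvature maximum (phase zero) after settling, with enough room after `t0`
#' for a pulse and the post-pulse cycles used by the phase-shift estimator.
#'
#' @param params a [model_params()] object.
#' @param dt integration step (s).
#' @param post_cycles number of cycles needed after the latest possible pulse.
#' @param thin storage thinning for the trajectory.
#' @return a list with the reference `traj`, `T0`, `t0` and `dt`, of class
#'   `osc_reference`.
#' @export
oscillator_reference <- function(params, dt = 5e-4, post_cycles = 13, thin = 1L) {
  if (!params_oscillatory(params))
    stop("parameters are non-oscillatory (P_th >= M0)")
  st <- ref_settings(params, dt)
  dur1 <- st$settle + 8 * st$T_guess
  tr <- simulate_free_running(params, duration = dur1, dt = dt, thin = thin)
  if (!attr(tr, "oscillatory")) stop("reference trajectory did not oscillate")
  ev <- attr(tr, "events")
  up <- ev$t[ev$sign == 1L]
  up <- up[up >= st$settle / 2]
  if (length(up) < 3) stop("too few cycles in reference pre-run")
  T0 <- mean(diff(up))

  # phase zero: ventral maximum following a switch to the dorsal-driving moment
  dn <- ev$t[ev$sign == -1L]
  dn <- dn[dn >= st$settle]
  if (!length(dn)) stop("no settled switch event found")
  t_ev <- dn[1]
  seg <- tr[tr$t >= t_ev - 0.05 * T0 & tr$t <= t_ev + 0.6 * T0, ]
  pk <- dense_maxima(seg$t, seg$K, min_height = -Inf)
  t0 <- if (length(pk)) pk[1] else {
    # at coarse storage the short post-switch rise can fall between samples;
    # take the largest stored sample instead
    seg$t[which.max(seg$K)]
  }

  dur <- t0 + (1 + post_cycles) * T0 + 1
  traj <- simulate_free_running(params, duration = dur, dt = dt, thin = thin)
  structure(list(traj = traj, T0 = T0, t0 = t0, dt = dt, params = params,
                 thin = thin),
            class = "osc_reference")
}

#' Simulate a transient muscle inhibition at a given phase
#'
#' Places a bell-shaped muscle-inhibition pulse at the requested phase of the
#' settled limit cycle (phase zero at the ventral curvature maximum) and
#' returns the perturbed trajectory together with an unperturbed reference on
#' the identical grid and initial state.
#'
#' @param params a [model_params()] object (must be oscillatory).
#' @param spec an [inhibition_spec()].
#' @param onset_phase pulse onset phase in `[0, 2pi)`.
#' @param reference optionally, a precomputed [oscillator_reference()]; reuse
#'   it across calls to avoid resimulating the reference.
#' @param dt integration step (s).
#' @param thin storage thinning.
#' @return an object of class `perturbed_pair`: a list with elements
#'   `reference`, `perturbed` (both `osc_traj` on the same grid), `pulse`
#'   (onset and end times, s), `onset_phase`, `T0` and `t0`.
#' @export
simulate_with_inhibition <- function(params, spec, onset_phase,
                                     reference = NULL, dt = 5e-4, thin = 1L) {
  stopifnot(inherits(spec, "inhibition_spec"))
  if (onset_phase < 0 || onset_phase >= 2 * pi)
    onset_phase <- onset_phase %% (2 * pi)
  if (is.null(reference))
    reference <- oscillator_reference(params, dt = dt, thin = thin)
  t_on <- reference$t0 + onset_phase / (2 * pi) * reference$T0
  dur <- max(reference$traj$t)
  pert <- simulate_free_running(reference$params, duration = dur,
                                dt = reference$dt, thin = reference$thin,
                                spec = spec, onsets = t_on)
  structure(list(reference = reference$traj, perturbed = pert,
                 pulse = c(onset = t_on, end = t_on + spec$pulse_duration),
                 onset_phase = onset_phase,
                 T0 = reference$T0, t0 = reference$t0),
            class = "perturbed_pair")
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- y[y <= -pi] + 2 * pi  # ties at -pi resolve to +pi
  y
}

# circular offsets of perturbed events relative to reference events, in rad
event_offsets <- function(ref_ev, pert_ev, T0) {
  vapply(ref_ev, function(tr) {
    d <- pert_ev - tr
    d <- d[abs(d) < 1.5 * T0]
    if (!length(d)) return(NA_real_)
    dd <- d[which.min(abs(wrap_pi(2 * pi * d / T0)))]
    wrap_pi(2 * pi * dd / T0)
  }, numeric(1))
}

#' Asymptotic phase shift of a perturbed trajectory
#'
#' Compares the timing of late oscillation events (switches to the
#' ventral-driving moment, one per cycle) between the perturbed and reference
#' trajectories, at least `skip_cycles` cycles after the pulse end, and
#' converts the mean timing offset to a phase shift
#' `dphi = 2 pi (t_perturbed - t_reference) / T0`, wrapped to `(-pi, pi]`.
#' Positive values are phase delays.
#'
#' @param pair a `perturbed_pair` from [simulate_with_inhibition()].
#' @param skip_cycles cycles after pulse end ignored while the oscillator
#'   relaxes back to its cycle.
#' @param measure_cycles number of late events averaged.
#' @return the phase shift (rad) in `(-pi, pi]`.
#' @export
asymptotic_phase_shift <- function(pair, skip_cycles = 5, measure_cycles = 5) {
  T0 <- pair$T0
  t_min <- pair$pulse["end"] + skip_cycles * T0
  ref_ev <- attr(pair$reference, "events")
  pert_ev <- attr(pair$perturbed, "events")
  if (is.null(pert_ev) || nrow(pert_ev) < 2 ||
      max(pert_ev$t) < t_min)
    stop("perturbed trajectory did not resume oscillation")
  r <- ref_ev$t[ref_ev$sign == 1L & ref_ev$t >= t_min]
  p <- pert_ev$t[pert_ev$sign == 1L]
  r <- head(r, measure_cycles)
  if (!length(r)) stop("not enough post-pulse cycles in the reference")
  off <- event_offsets(r, p, T0)
  off <- off[is.finite(off)]
  if (!length(off)) stop("no matching late events found")
  # circular mean, then wrap
  wrap_pi(atan2(mean(sin(off)), mean(cos(off))))
}

#' Model phase response curve
#'
#' Evaluates the asymptotic phase shift of the oscillator for pulses placed at
#' `n_phases` evenly spaced onset phases, reusing one settled reference
#' trajectory for all pulses.
#'
#' @param params a [model_params()] object.
#' @param spec an [inhibition_spec()].
#' @param n_phases number of onset phases (>= 32 recommended for locating the
#'   sawtooth transitions).
#' @param dt integration step (s).
#' @param reference optional precomputed [oscillator_reference()].
#' @param thin storage thinning used for the underlying simulations.
#' @return an object of class `prc_points`: a data frame with columns `phi`
#'   (onset phase, rad), `dphi` (shift, rad, positive = delay) and `weight`,
#'   with attribute `T0`.
#' @export
model_prc <- function(params, spec, n_phases = 64L, dt = 5e-4,
                      reference = NULL, thin = 10L) {
  if (n_phases < 4) stop("n_phases too small")
  if (is.null(reference))
    reference <- oscillator_reference(params, dt = dt, thin = thin)
  phis <- seq(0, 2 * pi, length.out = n_phases + 1L)[seq_len(n_phases)]
  prc_at_phases(params, spec, phis, reference)
}

# evaluate the model PRC at arbitrary onset phases, reusing one reference
prc_at_phases <- function(params, spec, phis, reference) {
  dphi <- vapply(phis, function(phi) {
    pair <- simulate_with_inhibition(params, spec, phi %% (2 * pi),
                                     reference = reference)
    asymptotic_phase_shift(pair)
  }, numeric(1))
  prc_points(phis, dphi, T0 = reference$T0)
}

#' @rdname model_prc
#' @details `single_side_prc()` is `model_prc()` with a single-side
#'   [inhibition_spec()]; it exists to mirror the one-sided illumination
#'   experiments, where the paralytic effect appears only while the
#'   illuminated side's muscles are driving the bend.
#' @export
single_side_prc <- function(params, spec, n_phases = 64L, dt = 5e-4,
                            reference = NULL, thin = 10L) {
  if (!spec$side %in% c("ventral", "dorsal"))
    stop("spec$side must be 'ventral' or 'dorsal'")
  model_prc(params, spec, n_phases = n_phases, dt = dt,
            reference = reference, thin = thin)
}

prc_points <- function(phi, dphi, weight = rep(1, length(phi)), T0 = NA_real_) {
  structure(data.frame(phi = phi %% (2 * pi), dphi = wrap_pi(dphi),
                       weight = weight),
            T0 = T0, class = c("prc_points", "data.frame"))
}

#' @export
plot.prc_points <- function(x, ...) {
  plot(x$phi, x$dphi, xlab = "inhibition phase (rad)",
       ylab = "phase shift (rad, + = delay)", ...)
  abline(h = 0, col = "grey70")
  invisible(x)
}

#' Timing of maximal paralysis after a pulse
#'
#' Reproduces, in the model, the behavioral observation that the head is most
#' paralyzed (straightest, i.e. closest to the phase-plane origin) a fraction
#' of a second after the light pulse ends. Paralysis depth is measured by the
#' normalized deviation `d` from the limit cycle ([deviation()]), which is
#' `-1` at the straight posture and `0` during normal undulation; unlike raw
#' `|K|`, it does not oscillate over the cycle, so the profile can be
#' averaged over pulses delivered at many onset phases without interference
#' from pulse-induced phase resetting. The time of maximal paralysis is the
#' minimum of the phase-averaged deviation profile.
#'
#' @param params a [model_params()] object.
#' @param spec an [inhibition_spec()].
#' @param n_phases number of onset phases averaged over.
#' @param window time span (s) after pulse onset to examine.
#' @param dt integration step (s).
#' @return a list with `t_min` (s from pulse end to maximal paralysis) and
#'   `profile` (data frame: time after onset, mean deviation `d`).
#' @export
paralysis_timing <- function(params, spec, n_phases = 24L, window = 2.5,
                             dt = 5e-4) {
  reference <- oscillator_reference(params, dt = dt)
  cycle <- extract_limit_cycle(reference$traj)
  phis <- seq(0, 2 * pi, length.out = n_phases + 1L)[seq_len(n_phases)]
  rel <- NULL
  acc <- NULL
  for (phi in phis) {
    pair <- simulate_with_inhibition(params, spec, phi, reference = reference)
    tr <- pair$perturbed
    sel <- which(tr$t >= pair$pulse["onset"] &
                   tr$t <= pair$pulse["onset"] + window)
    d <- deviation(tr$K[sel], tr$Kdot[sel], cycle)
    if (is.null(rel)) {
      rel <- tr$t[sel] - pair$pulse["onset"]
      acc <- d
    } else {
      n <- min(length(rel), length(d))
      acc <- acc[seq_len(n)] + d[seq_len(n)]
      rel <- rel[seq_len(n)]
    }
  }
  prof <- data.frame(t = rel, d = acc / n_phases)
  after <- prof[prof$t > spec$pulse_duration, ]
  i <- which.min(after$d)
  lag <- after$t[i] - spec$pulse_duration
  list(t_min = lag, profile = prof)
}

#' Phase of the model PRC's abrupt downward jump
#'
#' Locates the discontinuity of the model's phase response (the delay to
#' advance transition) by bisection on the onset phase: the shift changes by
#' the whole tooth height across the jump, so each bisection step needs only
#' one perturbed simulation.
#'
#' @param params a [model_params()].
#' @param spec an [inhibition_spec()].
#' @param bracket initial phase bracket containing exactly one jump.
#' @param tol phase tolerance (rad).
#' @param reference optional precomputed [oscillator_reference()].
#' @return the jump phase (rad).
#' @export
model_jump_phase <- function(params, spec, bracket = NULL, tol = 2e-3,
                             reference = NULL) {
  if (is.null(reference)) reference <- oscillator_reference(params, thin = 10L)
  shift_at <- function(phi) {
    pair <- simulate_with_inhibition(params, spec, phi %% (2 * pi),
                                     reference = reference)
    asymptotic_phase_shift(pair)
  }
  if (is.null(bracket)) {
    phis <- seq(0, 2 * pi, length.out = 17L)[1:16]
    v <- vapply(phis, shift_at, numeric(1))
    d <- v[c(2:16, 1)] - v
    i <- which.min(d)
    bracket <- c(phis[i], phis[i %% 16 + 1])
    if (bracket[2] < bracket[1]) bracket[2] <- bracket[2] + 2 * pi
  }
  lo <- bracket[1]; hi <- bracket[2]
  v_lo <- shift_at(lo); v_hi <- shift_at(hi)
  if (v_lo <= v_hi) stop("bracket does not contain a downward jump")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    v <- shift_at(mid)
    if (abs(v - v_lo) <= abs(v - v_hi)) { lo <- mid; v_lo <- v }
    else { hi <- mid; v_hi <- v }
  }
  ((lo + hi) / 2) %% (2 * pi)
}
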