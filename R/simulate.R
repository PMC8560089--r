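#' Simulate the free-running threshold-switch oscillator
#'
#' Integrates the curvature dynamics `tau_u dK/dt = Ma - K` and the muscle
#' moment `tau_m dMa/dt = Mt - Ma` with the hysteretic switching rule: the
#' target moment flips from `+M0` to `-M0` when the proprioceptive signal
#' `P = K + b dK/dt` crosses `+P_th` upward, and back when `P` crosses `-P_th`
#' downward. The moment equation is solved exactly between switches and the
#' curvature is advanced with fixed-step fourth-order Runge-Kutta; switch times
#' are located by linear interpolation of `P` within a step and the switch is
#' applied at the interpolated time.
#'
#' @param params a [model_params()] object.
#' @param duration simulated time (s); should be at least `10 * tau_u`.
#' @param dt integration step (s).
#' @param initial optional list with elements `K`, `Ma` and `Mt` (the sign of
#'   `Mt` is used). Default: `K = 0`, `Ma = Mt = +M0`.
#' @param thin store every `thin`-th integration step (events are always
#'   located at full resolution).
#' @param spec,onsets optional [inhibition_spec()] and pulse onset times (s);
#'   used internally by the perturbation machinery.
#' @return an object of class `osc_traj`: a data frame with columns
#'   `t, K, Kdot, Ma, Mt` and attributes `events` (data frame of interpolated
#'   switch times and the new target-moment sign), `dt`, `thin`, `oscillatory`
#'   and `params`. `oscillatory` is `FALSE` when fewer than two switches
#'   occurred within `duration` (e.g. when `P_th >= M0`).
#' @examples
#' tr <- simulate_free_running(model_params(), duration = 5)
#' nrow(switch_events(tr))
#' @export
simulate_free_running <- function(params, duration = 30, dt = 5e-4,
                                  initial = NULL, thin = 1L,
                                  spec = NULL, onsets = numeric(0)) {
  stopifnot(inherits(params, "model_params"))
  if (duration <= 0 || dt <= 0) stop("duration and dt must be positive")
  if (duration < 10 * params$tau_u)
    warning("duration < 10 * tau_u; transients may dominate")
  if (is.null(initial)) initial <- list(K = 0, Ma = params$M0, Mt = params$M0)
  mt0 <- if (initial$Mt >= 0) 1L else -1L

  res <- sim_threshold_cpp(params$tau_u, params$tau_m, params$M0, params$b,
                           params$P_th, duration, dt,
                           initial$K, initial$Ma, mt0,
                           env_list(spec, onsets), as.integer(thin))
  if (!res$ok) stop("integration produced non-finite state")
  traj <- data.frame(t = res$t, K = res$K, Kdot = res$Kdot,
                     Ma = res$Ma, Mt = res$Mt)
  ev <- data.frame(t = res$ev_t, sign = as.integer(res$ev_sign))
  structure(traj,
            events = ev, dt = dt, thin = as.integer(thin),
            oscillatory = nrow(ev) >= 2L,
            params = params,
            pulse = if (length(onsets)) cbind(onsets, onsets + spec$pulse_duration),
            class = c("osc_traj", "data.frame"))
}

#' Switch events and plateau durations of a trajectory
#'
#' @param traj an `osc_traj` from [simulate_free_running()].
#' @return a data frame with the interpolated switch times `t`, the new sign
#'   of the target moment, and `plateau`, the duration of the moment plateau
#'   that ended at each switch (NA for the first event). Empty if the
#'   trajectory never switched.
#' @export
switch_events <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev) || nrow(ev) == 0)
    return(data.frame(t = numeric(0), sign = integer(0), plateau = numeric(0)))
  ev$plateau <- c(NA_real_, diff(ev$t))
  ev
}

#' @export
print.osc_traj <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("Oscillator trajectory: %.3g s at dt = %.3g s (%d samples), %d switch events, oscillatory: %s\n",
              max(x$t), attr(x, "dt") * attr(x, "thin"), nrow(x),
              if (is.null(ev)) 0L else nrow(ev), attr(x, "oscillatory")))
  invisible(x)
}

#' @export
plot.osc_traj <- function(x, which = c("time", "portrait"), ...) {
  which <- match.arg(which)
  if (which == "time") {
    plot(x$t, x$K, type = "l", xlab = "time (s)", ylab = "scaled curvature K", ...)
    lines(x$t, x$Ma, col = "grey50", lty = 2)
    legend("topright", c("K", "Ma"), lty = c(1, 2), col = c("black", "grey50"),
           bty = "n")
  } else {
    plot(x$K, x$Kdot, type = "l", xlab = "K", ylab = "dK/dt (1/s)", ...)
  }
  invisible(x)
}

# local maxima of a dense, noise-free series; parabolic sub-sample refinement
dense_maxima <- function(t, K, min_height = 0.5 * max(K)) {
  n <- length(K)
  if (n < 3) return(numeric(0))
  idx <- which(K[2:(n - 1)] >= K[1:(n - 2)] & K[2:(n - 1)] > K[3:n]) + 1L
  idx <- idx[K[idx] >= min_height]
  if (!length(idx)) return(numeric(0))
  vapply(idx, function(i) {
    y1 <- K[i - 1]; y2 <- K[i]; y3 <- K[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den < 0) 0.5 * (y1 - y3) / den else 0
    t[i] + off * (t[i + 1] - t[i])
  }, numeric(1))
}

#' Extract the limit cycle of an oscillatory trajectory
#'
#' Discards the initial transient, measures the period as the mean interval
#' between every second switch event, and computes the cycle-average waveform
#' of `(K, dK/dt)` on a uniform phase grid with phase zero at the ventral
#' curvature maximum. Also reports the amplitude (maximum `|K|` of the average
#' waveform), and the fractions `U` (bending: `|K|` increasing) and `D`
#' (straightening: `|K|` decreasing) of the period.
#'
#' @param traj an oscillatory `osc_traj`.
#' @param discard fraction of the trajectory discarded as transient; the
#'   discard point is the larger of this fraction and five full cycles from
#'   the start (when available).
#' @param n_phase number of phase-grid points.
#' @return an object of class `limit_cycle`: a list with `period`, `phase`
#'   (grid in `[0, 2pi)`), `K`, `Kdot`, `amplitude`, `U`, `D`, `sd_K`,
#'   `sd_Kdot` and `n_cycles`.
#' @export
extract_limit_cycle <- function(traj, discard = 0.2, n_phase = 256L) {
  if (!isTRUE(attr(traj, "oscillatory")))
    stop("trajectory is not oscillatory")
  ev <- attr(traj, "events")
  dur <- max(traj$t)
  up <- ev$t[ev$sign == 1L]
  if (length(up) >= 6) {
    t_discard <- max(discard * dur, up[min(6, length(up))])
  } else {
    t_discard <- discard * dur
  }
  up_use <- up[up >= t_discard]
  if (length(up_use) < 6)
    stop("need at least 5 full cycles after transient discard")
  period <- mean(diff(up_use))

  keep <- traj$t >= t_discard
  tt <- traj$t[keep]; KK <- traj$K[keep]; KD <- traj$Kdot[keep]
  pk <- dense_maxima(tt, KK)
  if (length(pk) < 6) stop("too few ventral maxima after discard")

  grid <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  acc_K <- matrix(NA_real_, length(pk) - 1L, n_phase)
  acc_D <- acc_K
  for (j in seq_len(length(pk) - 1L)) {
    t0 <- pk[j]; t1 <- pk[j + 1L]
    tq <- t0 + grid / (2 * pi) * (t1 - t0)
    acc_K[j, ] <- approx(tt, KK, xout = tq, rule = 2)$y
    acc_D[j, ] <- approx(tt, KD, xout = tq, rule = 2)$y
  }
  Kbar <- colMeans(acc_K)
  Dbar <- colMeans(acc_D)
  prod <- Kbar * Dbar
  structure(list(period = period, phase = grid, K = Kbar, Kdot = Dbar,
                 amplitude = max(abs(Kbar)),
                 U = mean(prod > 0), D = mean(prod < 0),
                 sd_K = sd(Kbar), sd_Kdot = sd(Dbar),
                 n_cycles = length(pk) - 1L),
            class = "limit_cycle")
}

#' @export
print.limit_cycle <- function(x, ...) {
  cat(sprintf("Limit cycle: period %.4g s, amplitude %.4g, U = %.3f, D = %.3f (%d cycles averaged)\n",
              x$period, x$amplitude, x$U, x$D, x$n_cycles))
  invisible(x)
}

#' @export
plot.limit_cycle <- function(x, ...) {
  plot(x$K, x$Kdot, type = "l", xlab = "K", ylab = "dK/dt (1/s)", ...)
  invisible(x)
}
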