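#' Model parameters for the threshold-switch oscillator
#'
#' Bundles the five parameters of the relaxation oscillator: the bending
#' relaxation time scale `tau_u`, the muscle switching time scale `tau_m`, the
#' amplitude `M0` of the scaled active muscle moment, the proprioceptive
#' velocity weight `b`, and the proprioceptive threshold `P_th`. The defaults
#' are the values estimated for worms at the reference viscosity (120 mPa s):
#' `tau_u = 0.26` s, `tau_m = 0.1` s, `b = 0.046` s, `P_th = 2.33`, together
#' with `M0 = 3.5`, calibrated so that the free-running muscle-moment plateau
#' lasts about half a second.
#'
#' Positive scaled curvature denotes a ventral bend, and `Mt = +M0` is the
#' ventral-driving target moment.
#'
#' @param tau_u bending relaxation time scale (s).
#' @param tau_m muscle switching time scale (s); may be 0, in which case the
#'   active moment tracks the target moment instantaneously.
#' @param M0 amplitude of the scaled active muscle moment (dimensionless).
#' @param b proprioceptive velocity weight (s); must satisfy `b < tau_u`.
#' @param P_th proprioceptive threshold (dimensionless). If `P_th >= M0` the
#'   system has a stable fixed point instead of a limit cycle; this is allowed
#'   and flagged at simulation time, not an error here.
#' @return an object of class `model_params`.
#' @examples
#' p <- model_params()
#' switch_curvature(p)
#' @export
model_params <- function(tau_u = 0.26, tau_m = 0.1, M0 = 3.5,
                         b = 0.046, P_th = 2.33) {
  vals <- c(tau_u = tau_u, tau_m = tau_m, M0 = M0, b = b, P_th = P_th)
  if (any(!is.finite(vals)))
    stop("all model parameters must be finite")
  if (tau_u <= 0 || M0 <= 0 || P_th <= 0)
    stop("tau_u, M0 and P_th must be positive")
  if (tau_m < 0) stop("tau_m must be >= 0")
  if (b < 0) stop("b must be >= 0")
  if (b >= tau_u)
    stop("b must be smaller than tau_u (P would no longer be a posture signal)")
  structure(list(tau_u = tau_u, tau_m = tau_m, M0 = M0, b = b, P_th = P_th),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Threshold-switch oscillator parameters:\n")
  cat(sprintf("  tau_u = %.4g s, tau_m = %.4g s, M0 = %.4g, b = %.4g s, P_th = %.4g\n",
              x$tau_u, x$tau_m, x$M0, x$b, x$P_th))
  cat(sprintf("  oscillatory: %s (switch curvature K_sw = %.4g)\n",
              params_oscillatory(x),
              tryCatch(switch_curvature(x), error = function(e) NA_real_)))
  invisible(x)
}

#' Curvature at which the target moment switches
#'
#' In the limit of instantaneous muscle switching (`tau_m -> 0`) the active
#' moment sits at `+M0` while `P = K + b(M0 - K)/tau_u` rises toward the
#' threshold, so the switch occurs at curvature
#' `K_sw = (P_th - (b/tau_u) M0) / (1 - b/tau_u)`. With finite `tau_m` the
#' approach to the switch still happens on the moment plateau, so `K_sw`
#' remains an accurate description of the switch point.
#'
#' @param params a [model_params()] object.
#' @return the switch curvature (dimensionless).
#' @export
switch_curvature <- function(params) {
  r <- params$b / params$tau_u
  (params$P_th - r * params$M0) / (1 - r)
}

params_oscillatory <- function(params) {
  params$P_th < params$M0
}

#' Closed-form oscillation period in the instantaneous-muscle limit
#'
#' With `b >= 0` and `tau_m -> 0` the curvature relaxes exponentially toward
#' `-M0` (or `+M0`) between switches at `K = +/- K_sw`, giving the period
#' \deqn{T = 2\tau_u \log\frac{M_0 + K_{sw}}{M_0 - K_{sw}}.}
#' This serves as an independent analytic oracle for the simulator.
#'
#' @param params a [model_params()] object (its `tau_m` is ignored).
#' @return period (s).
#' @export
period_tau_m_zero <- function(params) {
  if (params$b >= params$tau_u) stop("degenerate: b must be < tau_u")
  ksw <- switch_curvature(params)
  if (ksw >= params$M0)
    stop("non-oscillatory: switch curvature reaches or exceeds M0")
  if (ksw <= 0)
    stop("switch curvature must be positive")
  2 * params$tau_u * log((params$M0 + ksw) / (params$M0 - ksw))
}

#' Specification of a transient muscle-inhibition pulse
#'
#' Describes one optogenetic muscle-inhibition pulse and the bell-shaped
#' suppression it induces. During the pulse-evoked paralysis the active moment
#' entering the curvature equation is multiplied by `1 - eps(t)` with the
#' Gaussian envelope
#' `eps(t) = depth * exp(-(t - (onset + peak_delay))^2 / (2 width^2))`,
#' truncated beyond five widths. `peak_delay` and `width` default to values
#' calibrated so that, for a 0.1 s pulse, the simulated head straightens most
#' (minimum bending amplitude) about 0.3 s after the end of the pulse, as
#' observed behaviorally.
#'
#' For single-side illumination the suppression is gated by the sign of the
#' active moment: `side = "ventral"` suppresses only while `Ma > 0` (ventral
#' muscles driving), `side = "dorsal"` only while `Ma < 0`, with the reduced
#' depth `depth_dorsal` (default `0.6 * depth`, reflecting the weaker dorsal
#' paralytic response).
#'
#' @param pulse_duration light-pulse duration (s); 0.1 s in the main
#'   experiments, 0.055 s in the short-pulse variant.
#' @param depth peak suppression, in `[0, 1]`.
#' @param peak_delay time from pulse onset to the envelope peak (s).
#' @param width Gaussian spread of the envelope (s).
#' @param side which muscles the light reaches: "both", "ventral" or "dorsal".
#' @param depth_dorsal peak suppression used for dorsal-side pulses.
#' @return an object of class `inhibition_spec`.
#' @export
inhibition_spec <- function(pulse_duration = 0.1, depth = 0.95,
                            peak_delay = 0.42, width = 0.04,
                            side = c("both", "ventral", "dorsal"),
                            depth_dorsal = 0.6 * depth) {
  side <- match.arg(side)
  if (depth < 0 || depth > 1) stop("depth must be in [0, 1]")
  if (depth_dorsal < 0 || depth_dorsal > 1) stop("depth_dorsal must be in [0, 1]")
  if (pulse_duration <= 0) stop("pulse_duration must be positive")
  if (width <= 0) stop("width must be positive")
  structure(list(pulse_duration = pulse_duration, depth = depth,
                 peak_delay = peak_delay, width = width, side = side,
                 depth_dorsal = depth_dorsal),
            class = "inhibition_spec")
}

#' @export
print.inhibition_spec <- function(x, ...) {
  cat(sprintf(
    "Inhibition pulse: %.3g s, side %s, depth %.3g (dorsal %.3g), peak delay %.3g s, width %.3g s\n",
    x$pulse_duration, x$side, x$depth, x$depth_dorsal, x$peak_delay, x$width))
  invisible(x)
}

#' Suppression envelope of a muscle-inhibition pulse
#'
#' Evaluates the bell-shaped suppression factor `eps(t)` for a pulse whose
#' light onset is at `onset` (s). The factor peaks at `spec$depth` at time
#' `onset + spec$peak_delay` and vanishes (exactly, by truncation at five
#' widths) far from the pulse.
#'
#' @param t times (s) at which to evaluate the envelope.
#' @param spec an [inhibition_spec()].
#' @param onset pulse onset time (s).
#' @return suppression factors in `[0, 1]`, same length as `t`.
#' @export
inhibition_envelope <- function(t, spec, onset = 0) {
  tc <- onset + spec$peak_delay
  u <- t - tc
  eps <- spec$depth * exp(-0.5 * (u / spec$width)^2)
  eps[abs(u) > 5 * spec$width] <- 0
  eps
}

env_side_code <- function(side) {
  match(side, c("both", "ventral", "dorsal")) - 1L
}

# envelope descriptor handed to the C++ integrators; tc are envelope centers
env_list <- function(spec = NULL, onsets = numeric(0)) {
  if (is.null(spec) || length(onsets) == 0)
    return(list(tc = numeric(0), depth = 0, width = 1,
                depth_dorsal = 0, side = 0L))
  list(tc = onsets + spec$peak_delay, depth = spec$depth, width = spec$width,
       depth_dorsal = spec$depth_dorsal, side = env_side_code(spec$side))
}
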