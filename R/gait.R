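# Gait adaptation to external viscosity. The mechanical load of the medium
# enters the model through the bending relaxation time constant tau_u.

#' Mapping from external viscosity to the bending relaxation time
#'
#' An affine map `tau_u(eta) = intercept + (tau_u_ref - intercept) *
#' (eta / eta_ref)`, anchored at the reference viscosity (120 mPa s, where
#' `tau_u = 0.26` s). The intercept represents internal (body) damping that
#' dominates at low external viscosity; a strictly proportional map would
#' drive `tau_u` below the proprioceptive velocity weight `b` in watery media
#' and destroy the oscillation, so the default keeps a 0.15 s internal floor
#' (which also puts the model's swimming frequency near 2 Hz in water).
#'
#' @param eta_ref reference viscosity (mPa s).
#' @param tau_u_ref bending relaxation time at `eta_ref` (s).
#' @param intercept internal-damping offset (s), `0 <= intercept < tau_u_ref`.
#' @return an object of class `viscosity_map`.
#' @export
viscosity_map <- function(eta_ref = 120, tau_u_ref = 0.26, intercept = 0.15) {
  if (eta_ref <= 0) stop("eta_ref must be positive")
  if (intercept < 0 || intercept >= tau_u_ref)
    stop("need 0 <= intercept < tau_u_ref")
  structure(list(eta_ref = eta_ref, tau_u_ref = tau_u_ref,
                 intercept = intercept),
            class = "viscosity_map")
}

#' @rdname viscosity_map
#' @param eta external viscosity (mPa s), positive.
#' @param map a `viscosity_map`.
#' @export
tau_u_of_eta <- function(eta, map = viscosity_map()) {
  if (any(eta <= 0)) stop("viscosity must be positive")
  map$intercept + (map$tau_u_ref - map$intercept) * eta / map$eta_ref
}

params_at_eta <- function(params, eta, map) {
  model_params(tau_u = tau_u_of_eta(eta, map), tau_m = params$tau_m,
               M0 = params$M0, b = params$b, P_th = params$P_th)
}

#' Frequency and amplitude across external viscosities
#'
#' For each viscosity, sets `tau_u = tau_u_of_eta(eta)`, simulates the free
#' running model and reports the undulation frequency `1/T0` (from switch
#' events) and the curvature amplitude (mean over cycles of the per-cycle
#' maximum `|K|`). Also records the curvature and the `|b dK/dt|` share of
#' the proprioceptive signal at the switch points, the quantities behind the
#' mechanistic reading of gait adaptation: at high load the velocity term
#' shrinks, so the worm must bend further before the threshold trips.
#'
#' @param etas viscosities (mPa s).
#' @param params base [model_params()] (its `tau_u` is replaced per eta).
#' @param map a [viscosity_map()].
#' @param n_cycles cycles simulated per viscosity after settling.
#' @param dt integration step (s).
#' @return data frame with columns `eta`, `tau_u`, `frequency_hz`,
#'   `amplitude`, `K_switch`, `bKdot_switch`, `oscillatory`.
#' @export
gait_scan <- function(etas, params = model_params(), map = viscosity_map(),
                      n_cycles = 15, dt = 5e-4) {
  rows <- lapply(etas, function(eta) {
    tau_u <- tau_u_of_eta(eta, map)
    if (params$b >= tau_u)
      return(data.frame(eta = eta, tau_u = tau_u, frequency_hz = NA_real_,
                        amplitude = NA_real_, K_switch = NA_real_,
                        bKdot_switch = NA_real_, oscillatory = FALSE))
    p <- params_at_eta(params, eta, map)
    T_guess <- tryCatch(period_tau_m_zero(p), error = function(e) NA_real_)
    if (!is.finite(T_guess)) T_guess <- 4 * p$tau_u
    dur <- (8 + n_cycles) * T_guess
    thin <- max(1L, floor(T_guess / dt / 2000))
    tr <- simulate_free_running(p, duration = dur, dt = dt, thin = thin)
    if (!attr(tr, "oscillatory"))
      return(data.frame(eta = eta, tau_u = tau_u, frequency_hz = NA_real_,
                        amplitude = NA_real_, K_switch = NA_real_,
                        bKdot_switch = NA_real_, oscillatory = FALSE))
    ev <- attr(tr, "events")
    up <- ev$t[ev$sign == 1]
    up <- up[up > 5 * T_guess]
    T0 <- mean(diff(up))
    # per-cycle maxima of |K| after settling
    keep <- tr$t > 5 * T_guess
    pk <- dense_maxima(tr$t[keep], abs(tr$K[keep]),
                       min_height = 0.5 * max(abs(tr$K[keep])))
    amp_cycles <- approx(tr$t, abs(tr$K), xout = pk)$y
    # state at settled switch events
    late_ev <- ev$t[ev$t > 5 * T_guess]
    Ksw <- abs(approx(tr$t, tr$K, xout = late_ev)$y)
    bKd <- abs(params$b * approx(tr$t, tr$Kdot, xout = late_ev)$y)
    data.frame(eta = eta, tau_u = tau_u, frequency_hz = 1 / T0,
               amplitude = mean(amp_cycles), K_switch = mean(Ksw),
               bKdot_switch = mean(bKd), oscillatory = TRUE)
  })
  do.call(rbind, rows)
}

#' Phases of the sawtooth's abrupt downward transitions
#'
#' Locates the `n` largest downward steps of a PRC sampled on an (assumed
#' even) phase grid and returns the midpoints between the flanking grid
#' phases, sorted.
#'
#' @param prc a `prc_points` data frame on an even phase grid.
#' @param n number of transitions to report.
#' @return transition phases (rad), sorted increasing.
#' @export
prc_transition_phases <- function(prc, n = 2L) {
  v <- prc$dphi
  ph <- prc$phi
  m <- length(v)
  step <- v[c(2:m, 1)] - v
  mid <- (ph + c(ph[2:m], ph[1] + 2 * pi)) / 2
  o <- order(step)[seq_len(n)]
  sort(mid[o] %% (2 * pi))
}

#' PRC as a function of external viscosity
#'
#' Computes the model PRC at each viscosity (with `tau_u` set by the map) and
#' reports the phases of the two abrupt downward transitions, which shift to
#' later phases as the load increases.
#'
#' @inheritParams gait_scan
#' @param spec an [inhibition_spec()].
#' @param n_phases phases per PRC.
#' @return a list with `prcs` (one `prc_points` per eta) and `transitions`
#'   (data frame: eta, first and second transition phase).
#' @export
prc_viscosity_scan <- function(etas, params = model_params(),
                               spec = inhibition_spec(),
                               map = viscosity_map(), n_phases = 64L,
                               dt = 5e-4) {
  prcs <- list()
  rows <- list()
  for (eta in etas) {
    p <- params_at_eta(params, eta, map)
    thin <- max(10L, floor(p$tau_u / 0.26 * 10))
    prc <- model_prc(p, spec, n_phases = n_phases, dt = dt,
                     reference = oscillator_reference(p, dt = dt, thin = thin))
    tp <- prc_transition_phases(prc)
    prcs[[as.character(eta)]] <- prc
    rows[[as.character(eta)]] <- data.frame(eta = eta, phi_jump1 = tp[1],
                                            phi_jump2 = tp[2])
  }
  list(prcs = prcs, transitions = do.call(rbind, c(rows, make.row.names = FALSE)))
}
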