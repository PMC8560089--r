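# Parameter estimation: direct estimation of (tau_u, tau_m, M0) from free
# locomotion, then a two-round fit of (b, P_th) and the inhibition envelope.

#' Configuration of the two-round fit
#'
#' @param b_range,pth_range search ranges for `b` (s) and `P_th`; when `NULL`
#'   they default to `(0.01, 0.7) * tau_u` and `(0.3, 0.97) * M0`.
#' @param n_grid grid resolution (b, P_th) for the round-1 coarse search.
#' @param polish run a Nelder-Mead refinement from the best grid cell.
#' @param n_eval_phases number of phases at which the model PRC is evaluated
#'   during round 2.
#' @param guard_tol round 2 may not worsen the round-1 waveform MSE by more
#'   than this amount when it co-refines `(b, P_th)`.
#' @return an object of class `fit_config`.
#' @export
fit_config <- function(b_range = NULL, pth_range = NULL, n_grid = c(21L, 21L),
                       polish = TRUE, n_eval_phases = 24L, guard_tol = 0.005) {
  structure(list(b_range = b_range, pth_range = pth_range,
                 n_grid = n_grid, polish = polish,
                 n_eval_phases = n_eval_phases, guard_tol = guard_tol),
            class = "fit_config")
}

# waveform of the trial set: per-worm cycle averages, averaged across worms
# on a common phase grid (all aligned at the ventral maximum)
pooled_cycle <- function(trials, n_phase = 256L, n_harm = 14L) {
  cycs <- list()
  for (tr in trials$trials) {
    if (tr$censored) next
    tt <- tr$t; KK <- tr$K
    if (!is.na(tr$pulse_start)) { # use only the clean pre-pulse window
      sel <- tt < tr$pulse_start
      tt <- tt[sel]; KK <- KK[sel]
    }
    cyc <- tryCatch(cycle_from_series(tt, KK, n_phase = n_phase,
                                      n_harm = n_harm),
                    error = function(e) NULL)
    if (!is.null(cyc)) cycs[[length(cycs) + 1L]] <- cyc
  }
  if (!length(cycs)) stop("no usable trials for a pooled waveform")
  Kbar <- rowMeans(vapply(cycs, `[[`, numeric(n_phase), "K"))
  period <- mean(vapply(cycs, `[[`, numeric(1), "period"))
  grid <- cycs[[1]]$phase
  dphi <- 2 * pi / n_phase
  Kdot <- (Kbar[c(2:n_phase, 1)] - Kbar[c(n_phase, 1:(n_phase - 1))]) /
    (2 * dphi) * (2 * pi / period)
  prod <- Kbar * Kdot
  structure(list(period = period, phase = grid, K = Kbar, Kdot = Kdot,
                 amplitude = max(abs(Kbar)), U = mean(prod > 0),
                 D = mean(prod < 0), sd_K = sd(Kbar), sd_Kdot = sd(Kdot),
                 n_cycles = sum(vapply(cycs, `[[`, integer(1), "n_cycles"))),
            class = "limit_cycle")
}

#' Direct estimation of tau_u, tau_m and M0 from free locomotion
#'
#' Per worm: the cycle-average curvature waveform is formed
#' ([cycle_from_series()]) and `(tau_u, tau_m, M0)` are estimated by fitting
#' the oscillator's waveform family to it ([fit_waveform_params()], the
#' `"waveform"` method of [estimate_tau_u()]). The returned values are
#' medians across worms. The switch curvature `K_sw`, a byproduct, is kept in
#' the per-worm table (it is the combination of `b` and `P_th` that free
#' locomotion determines).
#'
#' @param trials a `trial_set` of free-locomotion recordings (or trials whose
#'   pre-pulse windows are long enough).
#' @param maxit per-worm optimizer budget.
#' @return a list with `tau_u`, `tau_m`, `M0`, `K_sw` and a per-worm data
#'   frame `per_trial`.
#' @export
fit_direct <- function(trials, maxit = 200L) {
  rows <- list()
  for (tr in trials$trials) {
    if (tr$censored) next
    tt <- tr$t; KK <- tr$K
    if (!is.na(tr$pulse_start)) { sel <- tt < tr$pulse_start
      tt <- tt[sel]; KK <- KK[sel] }
    res <- tryCatch({
      cyc <- cycle_from_series(tt, KK, n_harm = 14L)
      f <- fit_waveform_params(cyc, maxit = maxit)
      data.frame(worm_id = tr$worm_id, trial_id = tr$trial_id,
                 tau_u = f$tau_u, tau_m = f$tau_m, M0 = f$M0,
                 K_sw = f$K_sw, mse = f$mse, period = cyc$period)
    }, error = function(e) NULL)
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (!length(rows)) stop("no trial yielded usable estimates")
  per <- do.call(rbind, c(rows, make.row.names = FALSE))
  list(tau_u = median(per$tau_u), tau_m = median(per$tau_m),
       M0 = median(per$M0), K_sw = median(per$K_sw), per_trial = per)
}

# circularly shift a cycle waveform so its curvature maximum (with parabolic
# sub-bin refinement) sits exactly at phase zero; removes residual alignment
# offsets before waveforms are compared
align_cycle <- function(cycle) {
  K <- cycle$K
  n <- length(K)
  i <- which.max(K)
  y1 <- K[if (i == 1) n else i - 1L]; y2 <- K[i]
  y3 <- K[if (i == n) 1L else i + 1L]
  den <- y1 - 2 * y2 + y3
  off <- if (den < 0) min(max(0.5 * (y1 - y3) / den, -0.5), 0.5) else 0
  shift <- (i - 1 + off) * 2 * pi / n
  # new waveform evaluated at (old phase = grid + shift), so the maximum
  # lands exactly on phase zero
  xq <- (cycle$phase + shift) %% (2 * pi)
  ph <- cycle$phase
  interp <- function(v) approx(c(ph - 2 * pi, ph, ph + 2 * pi),
                               rep(v, 3), xout = xq)$y
  cycle$K <- interp(K)
  cycle$Kdot <- interp(cycle$Kdot)
  cycle
}

#' Fit the oscillator's waveform family to an empirical cycle
#'
#' Least-squares fit of `(tau_u, tau_m, M0, K_sw)` to a cycle-average
#' curvature waveform, using the model itself as the waveform family: the
#' free-running waveform depends on `(b, P_th)` only through the switch
#' curvature `K_sw`, so simulations with `b = 0`, `P_th = K_sw` span the
#' whole family. The objective is the waveform MSE (phase-aligned at the
#' curvature maximum) plus a period-mismatch penalty.
#'
#' @param cycle an empirical `limit_cycle` (e.g. from [cycle_from_series()]).
#' @param init optional initial values (list with `tau_u`, `tau_m`, `M0`,
#'   `K_sw`).
#' @param maxit Nelder-Mead iteration budget.
#' @param period_weight weight of the squared relative period error.
#' @return a list with `tau_u`, `tau_m`, `M0`, `K_sw`, `mse`, `convergence`.
#' @export
# project a periodic waveform (uniform grid) onto its first H harmonics;
# used to compare model and data in the same frequency band
harmonic_project <- function(v, H) {
  n <- length(v)
  sp <- fft(v)
  keep <- c(seq_len(H + 1L), seq(n - H + 1L, n))
  sp[setdiff(seq_len(n), keep)] <- 0
  Re(fft(sp, inverse = TRUE)) / n
}

fit_waveform_params <- function(cycle, init = NULL, maxit = 150L,
                                period_weight = 50, deriv_weight = 0.2,
                                n_harm = NULL) {
  if (is.null(n_harm)) n_harm <- cycle$n_harm %||% 20L
  target <- align_cycle(cycle)
  Td <- target$period
  amp <- target$amplitude
  if (is.null(init))
    init <- list(tau_u = Td / 4, tau_m = Td / 10, M0 = 1.6 * amp,
                 K_sw = 0.97 * amp)
  unpack <- function(th) {
    M0 <- exp(th[3])
    list(tau_u = exp(th[1]), tau_m = exp(th[2]), M0 = M0,
         K_sw = M0 * stats::plogis(th[4]))
  }
  obj <- function(th) {
    u <- unpack(th)
    par <- tryCatch(model_params(tau_u = u$tau_u, tau_m = u$tau_m,
                                 M0 = u$M0, b = 0, P_th = u$K_sw),
                    error = function(e) NULL)
    if (is.null(par)) return(1e6)
    T_guess <- tryCatch(period_tau_m_zero(par), error = function(e) NA_real_)
    if (!is.finite(T_guess)) return(1e6)
    tr <- tryCatch(simulate_free_running(
      par, duration = 14 * (T_guess + 3 * u$tau_m), dt = 1e-3, thin = 5L),
      error = function(e) NULL)
    if (is.null(tr) || !attr(tr, "oscillatory")) return(1e6)
    cyc <- tryCatch(extract_limit_cycle(tr, n_phase = length(target$phase)),
                    error = function(e) NULL)
    if (is.null(cyc)) return(1e6)
    cyc <- align_cycle(cyc)
    # match the full phase portrait in the data's frequency band: the
    # derivative term (scaled to curvature units) pins down the transition
    # sharpness, i.e. tau_m and M0; band-limiting the model waveform to the
    # same number of harmonics as the empirical fit removes the Gibbs
    # mismatch at the switch kinks
    Km <- harmonic_project(cyc$K, n_harm)
    Dm <- harmonic_project(cyc$Kdot, n_harm)
    mean((Km - target$K)^2) +
      deriv_weight * (Td / (2 * pi))^2 * mean((Dm - target$Kdot)^2) +
      period_weight * (cyc$period / Td - 1)^2
  }
  run <- function(tau_a, tau_b) {
    th0 <- c(log(tau_a), log(tau_b), log(init$M0),
             stats::qlogis(min(max(init$K_sw / init$M0, 1e-3), 1 - 1e-3)))
    op <- optim(th0, obj, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-6))
    # restart from the solution: Nelder-Mead simplices collapse in narrow
    # curved valleys, and a fresh simplex reliably finishes the descent
    optim(op$par, obj, method = "Nelder-Mead",
          control = list(maxit = maxit, reltol = 1e-6))
  }
  # The tau_u = tau_m diagonal is a saddle of the exact swap symmetry of
  # the waveform family, where a start occasionally stalls; if the solution
  # sits suspiciously close to the diagonal, retry from the swapped start.
  op <- run(init$tau_u, init$tau_m)
  u <- unpack(op$par)
  if (min(u$tau_u, u$tau_m) / max(u$tau_u, u$tau_m) > 0.6) {
    op2 <- run(init$tau_m, init$tau_u)
    if (op2$value < op$value) op <- op2
    u <- unpack(op$par)
  }
  # The curvature waveform is exactly invariant under exchanging tau_u and
  # tau_m (two first-order filters in series commute), so the fit determines
  # the pair but not the order. Assign the labels physically: the true
  # active moment Ma = K + tau_u dK/dt saturates at its plateaus for a large
  # part of the cycle, whereas the swapped assignment's implied moment never
  # reaches them.
  sat_of <- function(tau)
    mean(abs(target$K + tau * target$Kdot) > 0.85 * u$M0)
  if (sat_of(u$tau_m) > sat_of(u$tau_u)) {
    tmp <- u$tau_u; u$tau_u <- u$tau_m; u$tau_m <- tmp
  }
  c(u, list(mse = op$value, convergence = op$convergence))
}

model_waveform_mse <- function(params, target_cycle, dt = 5e-4) {
  if (!params_oscillatory(params)) return(Inf)
  ksw <- switch_curvature(params)
  if (!is.finite(ksw) || ksw <= 0) return(Inf)
  T_guess <- tryCatch(period_tau_m_zero(params), error = function(e) NA_real_)
  if (!is.finite(T_guess)) return(Inf)
  tr <- tryCatch(simulate_free_running(
    params, duration = 17 * (T_guess + 3 * params$tau_m), dt = dt, thin = 5L),
    error = function(e) NULL)
  if (is.null(tr) || !attr(tr, "oscillatory")) return(Inf)
  cyc <- tryCatch(extract_limit_cycle(tr, n_phase = length(target_cycle$phase)),
                  error = function(e) NULL)
  if (is.null(cyc)) return(Inf)
  Km <- align_cycle(cyc)$K
  H <- target_cycle$n_harm
  if (!is.null(H)) Km <- harmonic_project(Km, H)
  mean((Km - align_cycle(target_cycle)$K)^2)
}

#' Round 1: fit (b, P_th) to the free-moving waveform
#'
#' Grid search plus optional Nelder-Mead polish minimizing the mean squared
#' error (K^2 units) between the model's cycle-average curvature waveform and
#' the target waveform, both phase-aligned at the ventral maximum, holding
#' `(tau_u, tau_m, M0)` fixed at their directly estimated values.
#'
#' Note on identifiability: between switches the dynamics do not involve
#' `b` or `P_th`; the waveform constrains them only through the switch
#' curvature `K_sw = (P_th - (b/tau_u) M0) / (1 - b/tau_u)`, so the round-1
#' objective has a nearly flat ridge along constant `K_sw`. Round 1 therefore
#' pins down `K_sw` precisely but `(b, P_th)` only up to that ridge; the PRC
#' (round 2) breaks the degeneracy, because during a pulse the moment deficit
#' makes the switch condition genuinely `b`-sensitive.
#'
#' @param target_cycle target `limit_cycle` (e.g. [pooled_cycle()] output).
#' @param fixed list with `tau_u`, `tau_m`, `M0`.
#' @param cfg a [fit_config()].
#' @return an object of class `fit_result`: list with `params` (full
#'   [model_params()]), `b`, `P_th`, `K_sw`, `mse`, and the searched grid.
#' @export
fit_round1 <- function(target_cycle, fixed, cfg = fit_config()) {
  if (sd(target_cycle$K) < 1e-8) stop("degenerate (constant) target waveform")
  b_range <- cfg$b_range
  if (is.null(b_range)) b_range <- c(0.01, 0.7) * fixed$tau_u
  pth_range <- cfg$pth_range
  if (is.null(pth_range)) pth_range <- c(0.3, 0.97) * fixed$M0
  bs <- seq(b_range[1], b_range[2], length.out = cfg$n_grid[1])
  ps <- seq(pth_range[1], pth_range[2], length.out = cfg$n_grid[2])
  obj <- function(b, pth) {
    par <- tryCatch(model_params(tau_u = fixed$tau_u, tau_m = fixed$tau_m,
                                 M0 = fixed$M0, b = b, P_th = pth),
                    error = function(e) NULL)
    if (is.null(par)) return(Inf)
    model_waveform_mse(par, target_cycle)
  }
  grid <- expand.grid(b = bs, P_th = ps)
  grid$mse <- mapply(obj, grid$b, grid$P_th)
  if (!any(is.finite(grid$mse)))
    stop("no oscillatory parameter combination in the search ranges")
  best <- grid[which.min(grid$mse), ]
  b_hat <- best$b; p_hat <- best$P_th; mse <- best$mse
  if (cfg$polish) {
    pen <- function(th) {
      b <- th[1]; pth <- th[2]
      if (b < b_range[1] || b > b_range[2] ||
          pth < pth_range[1] || pth > pth_range[2]) return(1e6)
      obj(b, pth)
    }
    op <- optim(c(b_hat, p_hat), pen, method = "Nelder-Mead",
                control = list(maxit = 120, reltol = 1e-4))
    if (is.finite(op$value) && op$value <= mse) {
      b_hat <- op$par[1]; p_hat <- op$par[2]; mse <- op$value
    }
  }
  params <- model_params(tau_u = fixed$tau_u, tau_m = fixed$tau_m,
                         M0 = fixed$M0, b = b_hat, P_th = p_hat)
  structure(list(params = params, b = b_hat, P_th = p_hat,
                 K_sw = switch_curvature(params), mse = mse, grid = grid),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result:\n")
  if (!is.null(x$b))
    cat(sprintf("  b = %.4g s, P_th = %.4g (K_sw = %.4g), waveform MSE = %.4g\n",
                x$b, x$P_th, x$K_sw, x$mse))
  if (!is.null(x$spec))
    cat(sprintf("  envelope: depth %.3g, peak delay %.3g s, width %.3g s; PRC MSE = %.4g\n",
                x$spec$depth, x$spec$peak_delay, x$spec$width, x$mse_prc))
  invisible(x)
}

#' Round 2: fit the inhibition envelope (and optionally b, P_th) to a PRC
#'
#' Minimizes the mean squared error (rad^2) between the model PRC and the
#' target PRC. Two target forms are supported:
#' \itemize{
#'   \item a `smoothed_prc`: the model PRC is evaluated at the target's grid
#'     phases and smeared with the same moving-average window before
#'     comparison (like with like);
#'   \item raw `prc_points` (per-trial points): the model PRC is evaluated
#'     on a fine phase grid, interpolated to every point's phase, and the MSE
#'     is taken over points. Near the sawtooth jumps this is far more
#'     informative than comparing bin means, because individual points
#'     localize the jump.
#' }
#'
#' By default only the envelope parameters `(depth, peak_delay, width)` are
#' refined, preserving the round-1 waveform fit exactly. With
#' `refine_bp = TRUE` the velocity weight `b` is co-refined and, when the
#' round-1 result carries a switch curvature `K_sw`, the threshold is tied to
#' the waveform ridge, `P_th = K_sw (1 - b/tau_u) + (b/tau_u) M0`: free
#' locomotion pins `K_sw` to a fraction of a percent, so the PRC only has to
#' determine `b` along that ridge. A penalty guards against the waveform MSE
#' deteriorating by more than `cfg$guard_tol`. Supplying `fix_peak_delay`
#' (e.g. calibrated against the observed paralysis lag with
#' [calibrate_peak_delay()]) removes the remaining degeneracy between the
#' envelope timing and `b`, which shift the PRC jump phases in the same way.
#'
#' @param target_prc target PRC: `smoothed_prc` or raw `prc_points`.
#' @param start a round-1 `fit_result` (or a [model_params()]).
#' @param spec0 starting [inhibition_spec()].
#' @param cfg a [fit_config()].
#' @param refine_bp co-refine `b` (and `P_th` via the ridge).
#' @param target_cycle required if `refine_bp`: the round-1 target waveform.
#' @param fix_peak_delay optional fixed envelope peak delay (s).
#' @param tie_pth tie `P_th` to the round-1 switch curvature (default: yes,
#'   whenever `start` provides `K_sw`).
#' @param maxit optimizer iterations.
#' @return a `fit_result` with elements `spec`, `params`, `mse_prc`,
#'   `mse_waveform`, `convergence`.
#' @export
fit_round2 <- function(target_prc, start, spec0 = inhibition_spec(),
                       cfg = fit_config(), refine_bp = FALSE,
                       target_cycle = NULL, fix_peak_delay = NULL,
                       fix_width = NULL, tie_pth = NULL, maxit = 150L) {
  params0 <- if (inherits(start, "fit_result")) start$params else start
  K_sw0 <- if (inherits(start, "fit_result")) start$K_sw else NULL
  if (is.null(tie_pth)) tie_pth <- refine_bp && !is.null(K_sw0)
  if (tie_pth && is.null(K_sw0)) stop("tie_pth needs a round-1 K_sw")
  if (refine_bp && tie_pth && !inherits(target_prc, "smoothed_prc") &&
      !is.null(target_prc$T0) && !is.null(fix_peak_delay))
    return(fit_round2_staged(target_prc, params0, K_sw0, spec0, cfg,
                             fix_peak_delay, fix_width, maxit))

  smoothed <- inherits(target_prc, "smoothed_prc")
  use <- if ("ok" %in% names(target_prc)) which(target_prc$ok) else
    seq_len(nrow(target_prc))
  pt_phi <- target_prc$phi[use]
  pt_dphi <- target_prc$dphi[use]
  if (smoothed) {
    phis <- pt_phi
    if (length(phis) > cfg$n_eval_phases) {
      idx <- round(seq(1, length(phis), length.out = cfg$n_eval_phases))
      phis <- phis[idx]; pt_dphi <- pt_dphi[idx]; pt_phi <- phis
    }
    smooth_bw <- attr(target_prc, "bin_width") %||% (0.16 * pi)
  } else {
    n_grid <- max(48L, cfg$n_eval_phases)
    phis <- seq(0, 2 * pi, length.out = n_grid + 1L)[seq_len(n_grid)]
    smooth_bw <- NULL
  }
  # Per-worm period correction for raw points: the sawtooth jump of worm w
  # sits at phi_sw - 2 pi t_c / T0_w (t_c = time of peak suppression after
  # onset), so pooling worms with different periods blurs the jumps. Each
  # point's phase is compared against the model curve shifted by the exact
  # first-order correction for its worm's measured period.
  t_c <- if (!is.null(fix_peak_delay)) fix_peak_delay else spec0$peak_delay
  phase_corr <- if (!smoothed && !is.null(target_prc$T0)) {
    T0w <- target_prc$T0[use]
    2 * pi * t_c * (1 / T0w - 1 / median(T0w))
  } else 0
  model_dphi_at_points <- function(prc) {
    if (smoothed)
      return(smooth_prc(prc, bin_width = smooth_bw, grid = phis,
                        min_pts = 1L)$dphi)
    approx(c(prc$phi - 2 * pi, prc$phi, prc$phi + 2 * pi),
           rep(prc$dphi, 3), xout = (pt_phi + phase_corr) %% (2 * pi),
           rule = 2)$y
  }

  b_range <- cfg$b_range
  if (is.null(b_range)) b_range <- c(0.01, 0.7) * params0$tau_u
  pth_range <- cfg$pth_range
  if (is.null(pth_range)) pth_range <- c(0.3, 0.97) * params0$M0

  wmse0 <- if (refine_bp) {
    if (is.null(target_cycle)) stop("refine_bp = TRUE needs target_cycle")
    model_waveform_mse(params0, target_cycle)
  } else NA_real_

  ref_cache <- if (!refine_bp)
    oscillator_reference(params0, thin = 10L) else NULL

  fit_pd <- is.null(fix_peak_delay)
  fit_w <- is.null(fix_width)
  unpack <- function(th) {
    spec <- spec0
    spec$depth <- stats::plogis(th[1])
    i <- 2L
    if (fit_pd) { spec$peak_delay <- exp(th[i]); i <- i + 1L }
    else spec$peak_delay <- fix_peak_delay
    if (fit_w) { spec$width <- exp(th[i]); i <- i + 1L }
    else spec$width <- fix_width
    spec$depth_dorsal <- 0.6 * spec$depth
    par <- params0
    if (refine_bp) {
      b <- b_range[1] + diff(b_range) * stats::plogis(th[i])
      pth <- if (tie_pth) {
        r <- b / params0$tau_u
        K_sw0 * (1 - r) + r * params0$M0
      } else {
        pth_range[1] + diff(pth_range) * stats::plogis(th[i + 1L])
      }
      par <- tryCatch(model_params(
        tau_u = params0$tau_u, tau_m = params0$tau_m, M0 = params0$M0,
        b = b, P_th = pth), error = function(e) NULL)
    }
    list(spec = spec, params = par)
  }
  n_eval <- 0L
  objective <- function(th) {
    u <- unpack(th)
    if (is.null(u$params) || !params_oscillatory(u$params)) return(1e6)
    n_eval <<- n_eval + 1L
    ref <- if (refine_bp)
      tryCatch(oscillator_reference(u$params, thin = 10L),
               error = function(e) NULL) else ref_cache
    if (is.null(ref)) return(1e6)
    prc <- tryCatch(prc_at_phases(u$params, u$spec, phis, ref),
                    error = function(e) NULL)
    if (is.null(prc)) return(1e6)
    mse <- mean((model_dphi_at_points(prc) - pt_dphi)^2)
    if (refine_bp && !tie_pth) {
      wm <- model_waveform_mse(u$params, target_cycle)
      mse <- mse + 50 * max(0, wm - wmse0 - cfg$guard_tol)^2
    }
    mse
  }
  th0 <- c(stats::qlogis(min(max(spec0$depth, 1e-3), 1 - 1e-3)),
           if (fit_pd) log(spec0$peak_delay) else NULL,
           if (fit_w) log(spec0$width) else NULL)
  if (refine_bp) {
    f <- function(v, r) stats::qlogis(min(max((v - r[1]) / diff(r), 1e-3),
                                          1 - 1e-3))
    # the objective is plateau-like in b away from the jump-alignment basin,
    # so pick the starting b by a coarse 1-D scan instead of trusting the
    # (ridge-degenerate) round-1 value
    b_start <- params0$b
    if (length(pt_phi) >= 10) {
      cand <- exp(seq(log(max(b_range[1], 1e-3)), log(b_range[2]),
                      length.out = 7L))
      vals <- vapply(cand, function(bc)
        objective(c(th0, f(bc, b_range),
                    if (!tie_pth) f(params0$P_th, pth_range) else NULL)),
        numeric(1))
      b_start <- cand[which.min(vals)]
    }
    th0 <- c(th0, f(b_start, b_range),
             if (!tie_pth) f(params0$P_th, pth_range) else NULL)
  }
  if (length(th0) == 1L) {
    op <- optim(th0, objective, method = "Brent",
                lower = stats::qlogis(1e-3), upper = stats::qlogis(1 - 1e-3))
  } else {
    op <- optim(th0, objective, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-4))
    op <- optim(op$par, objective, method = "Nelder-Mead",
                control = list(maxit = maxit, reltol = 1e-4))
  }
  u <- unpack(op$par)
  structure(list(spec = u$spec, params = u$params, mse_prc = op$value,
                 mse_waveform = if (refine_bp)
                   model_waveform_mse(u$params, target_cycle) else wmse0,
                 b = u$params$b, P_th = u$params$P_th,
                 K_sw = switch_curvature(u$params),
                 convergence = op$convergence, n_eval = n_eval),
            class = "fit_result")
}


# Staged refinement for raw per-trial PRC points with a known envelope peak
# time: (1) fit the envelope amplitude parameters with b held midrange,
# (2) localize the empirical sawtooth jumps by change-point regression and
# solve b so the model jump (found by bisection) matches, with P_th tied to
# the round-1 switch curvature, (3) refit the envelope at the solved b.
# This sidesteps the multi-basin joint objective: the jumps carry nearly all
# of the b information in the PRC.
fit_round2_staged <- function(target_prc, params0, K_sw0, spec0, cfg,
                              fix_peak_delay, fix_width, maxit) {
  tau_u <- params0$tau_u; M0 <- params0$M0
  b_range <- cfg$b_range
  if (is.null(b_range)) b_range <- c(0.01, 0.7) * tau_u
  params_at_b <- function(b) {
    b <- min(max(b, b_range[1]), b_range[2])
    r <- b / tau_u
    model_params(tau_u = tau_u, tau_m = params0$tau_m, M0 = M0,
                 b = b, P_th = K_sw0 * (1 - r) + r * M0)
  }
  fit_env <- function(par, spec_init, maxit_env = 60L) {
    fit_round2(target_prc, par, spec0 = spec_init, cfg = cfg,
               refine_bp = FALSE, fix_peak_delay = fix_peak_delay,
               fix_width = fix_width, maxit = maxit_env)
  }
  J_emp <- as.numeric(estimate_prc_jumps(target_prc, t_c = fix_peak_delay))
  b <- sqrt(prod(b_range))
  env <- NULL
  spec_cur <- spec0
  # alternate: fit the suppression depth at the current b, then re-solve b
  # so the model's jump matches the empirical one
  for (outer in 1:2) {
    env <- fit_env(params_at_b(b), spec_cur)
    spec_cur <- env$spec
    b_prev <- NA_real_; J_prev <- NA_real_
    for (it in 1:4) {
      par <- params_at_b(b)
      J_mod <- tryCatch(model_jump_phase(par, spec_cur),
                        error = function(e) NA)
      if (!is.finite(J_mod)) break
      err <- wrap_pi(2 * ((J_mod - J_emp) %% pi)) / 2  # compare modulo pi
      if (abs(err) < 0.005) break
      slope <- 3  # d(jump phase)/db, rad per unit b; refined in iteration
      if (is.finite(b_prev) && abs(b - b_prev) > 1e-4) {
        e_prev <- wrap_pi(2 * ((J_prev - J_emp) %% pi)) / 2
        sl <- (err - e_prev) / (b - b_prev)
        if (is.finite(sl) && sl > 0.5) slope <- sl
      }
      b_prev <- b; J_prev <- J_mod
      b <- min(max(b - err / slope, b_range[1]), b_range[2])
    }
  }
  par <- params_at_b(b)
  env2 <- fit_env(par, spec_cur, maxit_env = maxit)
  structure(list(spec = env2$spec, params = par, mse_prc = env2$mse_prc,
                 mse_waveform = NA_real_, b = par$b, P_th = par$P_th,
                 K_sw = switch_curvature(par), J_emp = J_emp,
                 convergence = env2$convergence, n_eval = env2$n_eval),
            class = "fit_result")
}

#' Parameter-recovery experiment on synthetic data
#'
#' End-to-end validation harness: generates synthetic free-locomotion and
#' perturbation data with known ground truth, runs the direct estimators and
#' the two-round fit, and tabulates true versus recovered parameters across
#' replicates and noise levels.
#'
#' @param seed base seed; replicate r at noise level j uses a seed derived
#'   from it.
#' @param noise_levels observation-noise standard deviations to test.
#' @param n_reps replicates per noise level.
#' @param n_worms_free,n_worms_prc worms per synthetic data set.
#' @param free_duration seconds of free locomotion per worm.
#' @param cfg a [fit_config()].
#' @param params generating [model_params()].
#' @param spec generating [inhibition_spec()].
#' @return a data frame with columns `noise_sd`, `rep`, `param`, `true`,
#'   `est`.
#' @export
parameter_recovery_experiment <- function(seed = 1L, noise_levels = 0.1,
                                          n_reps = 10L, n_worms_free = 4L,
                                          n_worms_prc = 20L,
                                          free_duration = 50,
                                          cfg = fit_config(n_grid = c(15L, 15L)),
                                          params = model_params(),
                                          spec = inhibition_spec()) {
  rows <- list()
  for (j in seq_along(noise_levels)) {
    ns <- noise_levels[j]
    for (r in seq_len(n_reps)) {
      sub <- worm_seed(seed, 1000 * j + r)
      cfg_free <- synth_config(n_worms = n_worms_free, noise_sd = ns,
                               seed = sub, params = params, spec = spec,
                               free_duration = free_duration)
      free <- generate_free_recording(cfg_free)
      direct <- fit_direct(free)
      wave <- pooled_cycle(free)
      r1 <- fit_round1(wave, direct, cfg)
      cfg_prc <- synth_config(n_worms = n_worms_prc, noise_sd = ns,
                              seed = sub + 1L, params = params, spec = spec)
      prc_data <- generate_prc_experiment(cfg_prc)
      pts <- analyze_trials(prc_data)
      # Match the model's free-running period to the empirically measured
      # one before the PRC round: jump phases scale like t_effect / T0, so
      # a percent-level period mismatch would otherwise be absorbed by b.
      T_tgt <- median(pts$T0)
      par_adj <- r1$params
      for (it in 1:2) {
        refA <- oscillator_reference(par_adj, thin = 10L)
        par_adj <- model_params(tau_u = par_adj$tau_u * T_tgt / refA$T0,
                                tau_m = par_adj$tau_m, M0 = par_adj$M0,
                                b = par_adj$b, P_th = par_adj$P_th)
      }
      r1_adj <- r1
      r1_adj$params <- par_adj
      # The envelope peak time is treated as known apparatus calibration
      # (the generator's own value): the PRC jump phases depend on the sum
      # of the suppression delay and the b-induced shift, so b is
      # identifiable from the PRC only when the envelope timing is supplied
      # independently (see the methods vignette).
      spec0 <- spec
      spec0$depth <- 0.8
      r2 <- fit_round2(pts, r1_adj, spec0 = spec0, cfg = cfg,
                       refine_bp = TRUE, target_cycle = wave,
                       fix_peak_delay = spec$peak_delay,
                       fix_width = spec$width, maxit = 120L)
      est <- c(tau_u = direct$tau_u, tau_m = direct$tau_m, M0 = direct$M0,
               b = r2$b, P_th = r2$P_th)
      tru <- c(tau_u = params$tau_u, tau_m = params$tau_m, M0 = params$M0,
               b = params$b, P_th = params$P_th)
      rows[[length(rows) + 1L]] <-
        data.frame(noise_sd = ns, rep = r, param = names(est),
                   true = unname(tru[names(est)]), est = unname(est))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
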