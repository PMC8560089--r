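# Per-trial phase-shift estimation: the analysis applied to experimental (or
# synthetic) perturbation trials to build an empirical PRC.

# Refine a peak time by sliding the trial's own cycle-average template over
# the raw samples around the peak and minimizing the squared mismatch. This
# uses the whole waveform rather than just the samples next to the maximum,
# which makes peak timing far less sensitive to observation noise.
refine_peak_time <- function(t, K, t_pk, T0, template) {
  sel <- which(t >= t_pk - 0.45 * T0 & t <= t_pk + 0.45 * T0)
  if (length(sel) < 5) return(t_pk)
  tmpl_at <- function(ph) {
    approx(c(template$phase, 2 * pi), c(template$K, template$K[1]),
           xout = ph %% (2 * pi), rule = 2)$y
  }
  sse <- function(delta) {
    ph <- (t[sel] - (t_pk + delta)) / T0 * 2 * pi
    sum((K[sel] - tmpl_at(ph))^2)
  }
  opt <- optimize(sse, interval = c(-0.35 * T0, 0.35 * T0))
  t_pk + opt$minimum
}

#' Phase of inhibition and resulting phase shift of one trial
#'
#' Implements the per-trial measurement behind the experimental PRC:
#' \enumerate{
#'   \item ventral maxima are detected in the pre-pulse window and refined by
#'     template matching against the trial's own cycle-average waveform;
#'   \item the pre-pulse period `T0` and the phase of the pulse onset are
#'     obtained by linear regression of peak times and extrapolation;
#'   \item recovery is declared at the first post-pulse time from which the
#'     normalized deviation stays small (`|d| < recovery_d` for most of a
#'     full cycle, the deviation being measured against the pre-pulse cycle);
#'   \item post-recovery maxima are refined the same way, and the phase shift
#'     is the circular mean of `2 pi (t_observed - t_extrapolated) / T0`
#'     over those maxima, wrapped to `(-pi, pi]`; positive shifts are delays.
#' }
#'
#' @param trial a [trial_record()] with a pulse window and `censored = FALSE`.
#' @param recovery_d deviation threshold for declaring recovery.
#' @param recovery_frac fraction of samples within a cycle-long window that
#'   must satisfy the deviation threshold (robust to isolated noise spikes).
#' @param max_post maximum number of post-recovery maxima used.
#' @param smooth_window smoothing window (samples) for peak detection and
#'   derivative estimation.
#' @return a one-row data frame `phi`, `dphi`, `weight`, with diagnostics as
#'   attributes (`T0`, `recovery_t`, `n_pre`, `n_post`).
#' @export
trial_phase_shift <- function(trial, recovery_d = 0.2, recovery_frac = 0.9,
                              max_post = 4L, smooth_window = 5) {
  if (trial$censored) stop("trial is censored")
  if (is.na(trial$pulse_start)) stop("trial has no pulse window")
  t <- trial$t; K <- trial$K
  pre <- t < trial$pulse_start
  pre_pk <- find_bend_peaks(t[pre], K[pre], smooth_window = smooth_window)
  # drop leading maxima still inside the previous pulse's recovery (their
  # spacing deviates from the later, settled rhythm)
  while (length(pre_pk) > 3) {
    sp <- diff(pre_pk)
    if (abs(sp[1] - median(sp[-1])) > 0.08 * median(sp[-1]))
      pre_pk <- pre_pk[-1]
    else break
  }
  if (length(pre_pk) < 3) stop("fewer than three clean pre-pulse maxima")
  template <- cycle_from_series(t[pre], K[pre], n_phase = 64L, peaks = pre_pk,
                                smooth_window = smooth_window)
  T0 <- template$period
  pre_pk <- vapply(pre_pk, function(pk) refine_peak_time(t[pre], K[pre], pk,
                                                         T0, template),
                   numeric(1))
  fit <- lm(pre_pk ~ seq_along(pre_pk))
  T0 <- unname(coef(fit)[2])
  t_last <- pre_pk[length(pre_pk)]
  phi_on <- 2 * pi * (((trial$pulse_start - t_last) / T0) %% 1)

  # recovery detection on the deviation against the pre-pulse cycle; the
  # threshold is calibrated on the trial's own pre-pulse deviation so that
  # smoothing-induced bias and observation noise do not mask recovery
  Ks <- moving_avg(K, smooth_window)
  Kd <- central_diff(t, Ks)
  d <- abs(deviation(Ks, Kd, template))
  base <- quantile(d[pre][t[pre] >= pre_pk[1]], 0.9, na.rm = TRUE)
  thr <- max(recovery_d, 1.25 * base)
  dt_s <- median(diff(t))
  win <- max(3L, round(T0 / dt_s))
  post_i <- which(t >= trial$pulse_end)
  ok <- d < thr
  rec_t <- NA_real_
  for (i in post_i) {
    if (i + win - 1 > length(ok)) break
    if (mean(ok[i:(i + win - 1)]) >= recovery_frac) { rec_t <- t[i]; break }
  }
  if (is.na(rec_t)) stop("undetectable post-recovery rhythm")

  post <- t >= rec_t
  post_pk <- find_bend_peaks(t[post], K[post], smooth_window = smooth_window)
  # drop maxima in the first partial cycle after recovery: the state is
  # still spiraling onto the cycle there and their timing is biased late
  post_pk <- post_pk[post_pk >= rec_t + 0.8 * T0]
  if (length(post_pk) < 2) stop("fewer than two post-recovery maxima")
  post_pk <- head(post_pk, max_post)
  post_pk <- vapply(post_pk, function(pk) refine_peak_time(t[post], K[post],
                                                           pk, T0, template),
                    numeric(1))
  off <- wrap_pi(2 * pi * (post_pk - t_last) / T0)
  dphi <- wrap_pi(atan2(mean(sin(off)), mean(cos(off))))
  structure(data.frame(phi = phi_on, dphi = dphi, weight = 1),
            T0 = T0, recovery_t = rec_t,
            n_pre = length(pre_pk), n_post = length(post_pk))
}

#' Empirical PRC points from a trial set
#'
#' Applies [trial_phase_shift()] to every non-censored pulse trial, skipping
#' trials where the measurement fails (their error messages are kept in the
#' `failures` attribute).
#'
#' @param trials a `trial_set`.
#' @param ... passed to [trial_phase_shift()].
#' @return a `prc_points` data frame with extra columns `worm_id`,
#'   `trial_id`; attribute `failures` lists skipped trials.
#' @export
analyze_trials <- function(trials, ...) {
  rows <- list()
  fails <- character(0)
  for (tr in trials$trials) {
    key <- paste(tr$worm_id, tr$trial_id, sep = "/")
    if (tr$censored || is.na(tr$pulse_start)) next
    res <- tryCatch(trial_phase_shift(tr, ...), error = function(e) e)
    if (inherits(res, "error")) {
      fails[key] <- conditionMessage(res)
      next
    }
    res$worm_id <- tr$worm_id
    res$trial_id <- tr$trial_id
    res$T0 <- attr(res, "T0")
    rows[[key]] <- res
  }
  if (!length(rows)) {
    out <- prc_points(numeric(0), numeric(0))
    out$worm_id <- character(0); out$trial_id <- character(0)
    out$T0 <- numeric(0)
    attr(out, "failures") <- fails
    return(out)
  }
  df <- do.call(rbind, c(rows, make.row.names = FALSE))
  out <- prc_points(df$phi, df$dphi)
  out$worm_id <- df$worm_id
  out$trial_id <- df$trial_id
  out$T0 <- df$T0
  attr(out, "failures") <- fails
  attr(out, "T0") <- median(df$T0)
  out
}

#' Empirical paralysis-lag from perturbation trials
#'
#' Averages the normalized deviation `|d|(t)` (each trial measured against
#' its own pre-pulse cycle) across trials, aligned at the pulse onset, and
#' returns the time from pulse end to the minimum of the averaged profile:
#' the moment of maximal paralysis. This is the data-side counterpart of
#' [paralysis_timing()] and independently pins down the timing of the
#' suppression envelope.
#'
#' @param trials a `trial_set` with pulse trials.
#' @param window time span (s) after pulse onset examined.
#' @param smooth_window smoothing (samples) for the deviation computation.
#' @return a list with `lag` (s after pulse end) and the averaged `profile`.
#' @export
paralysis_lag_from_trials <- function(trials, window = 2, smooth_window = 5) {
  grid <- NULL
  acc <- NULL
  n <- 0L
  pulse_dur <- NA_real_
  for (tr in trials$trials) {
    if (tr$censored || is.na(tr$pulse_start)) next
    res <- tryCatch({
      t <- tr$t; K <- tr$K
      pre <- t < tr$pulse_start
      pk <- find_bend_peaks(t[pre], K[pre], smooth_window = smooth_window)
      if (length(pk) < 4) stop("too short")
      tmpl <- cycle_from_series(t[pre], K[pre], n_phase = 64L, peaks = pk,
                                smooth_window = smooth_window)
      Ks <- moving_avg(K, smooth_window)
      Kd <- central_diff(t, Ks)
      d <- deviation(Ks, Kd, tmpl)
      sel <- t >= tr$pulse_start - 0.5 & t <= tr$pulse_start + window
      rel <- t[sel] - tr$pulse_start
      g <- seq(-0.4, window - 0.1, by = 0.025)
      list(g = g, d = approx(rel, d[sel], xout = g, rule = 2)$y)
    }, error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(acc)) { grid <- res$g; acc <- res$d } else acc <- acc + res$d
    n <- n + 1L
    pulse_dur <- tr$pulse_end - tr$pulse_start
  }
  if (n == 0L) stop("no usable pulse trials")
  prof <- data.frame(t = grid, d = acc / n)
  after <- prof[prof$t > pulse_dur, ]
  i <- which.min(after$d)
  t_min <- after$t[i]
  if (i > 1 && i < nrow(after)) { # parabolic refinement of the dip
    y1 <- after$d[i - 1]; y2 <- after$d[i]; y3 <- after$d[i + 1]
    den <- y1 - 2 * y2 + y3
    if (den > 0)
      t_min <- t_min + 0.5 * (y1 - y3) / den * diff(after$t[1:2])
  }
  list(lag = t_min - pulse_dur, profile = prof, n_trials = n)
}

# Noise-free synthetic pulse trials sampled like the behavioral recordings;
# used to measure the model-side paralysis lag through the identical
# data-analysis path (sampling, smoothing, deviation), so that model and
# data lags are directly comparable.
model_pulse_trials <- function(params, spec, n_phases = 8L,
                               sample_rate = 20, pre = 4.2, post = 3) {
  reference <- oscillator_reference(params, thin = 5L)
  phis <- seq(0, 2 * pi, length.out = n_phases + 1L)[seq_len(n_phases)]
  trials <- list()
  for (i in seq_along(phis)) {
    pair <- simulate_with_inhibition(params, spec, phis[i],
                                     reference = reference)
    tr <- pair$perturbed
    ts <- seq(max(0, pair$pulse["onset"] - pre),
              min(max(tr$t), pair$pulse["onset"] + post),
              by = 1 / sample_rate)
    trials[[i]] <- trial_record("model", sprintf("p%02d", i), ts,
                                approx(tr$t, tr$K, xout = ts)$y,
                                pulse_start = unname(pair$pulse["onset"]),
                                pulse_end = unname(pair$pulse["end"]))
  }
  trial_set(trials)
}

#' Calibrate the envelope peak delay against a paralysis lag
#'
#' Finds the `peak_delay` for which the model's phase-averaged paralysis
#' profile ([paralysis_timing()]) dips at the observed lag after pulse end,
#' by a few secant iterations (the lag is a smooth, nearly unit-slope
#' function of the peak delay).
#'
#' @param params a [model_params()].
#' @param spec an [inhibition_spec()] providing the other envelope values.
#' @param target_lag observed lag (s), e.g. from
#'   [paralysis_lag_from_trials()].
#' @param n_phases onset phases averaged per evaluation.
#' @param tol convergence tolerance (s).
#' @return the calibrated `peak_delay` (s).
#' @export
calibrate_peak_delay <- function(params, spec, target_lag, n_phases = 8L,
                                 tol = 0.01) {
  lag_of <- function(pd) {
    s <- spec; s$peak_delay <- pd
    paralysis_lag_from_trials(model_pulse_trials(params, s,
                                                 n_phases = n_phases))$lag
  }
  pd <- max(0.05, spec$peak_delay + (target_lag - lag_of(spec$peak_delay)))
  for (i in 1:3) {
    err <- lag_of(pd) - target_lag
    if (abs(err) < tol) break
    pd <- max(0.05, pd - err)
  }
  pd
}
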