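# Synthetic free-locomotion recordings and perturbation-trial sets with the
# structure of the behavioral experiments and exact ground truth, so that the
# whole analysis pipeline can be exercised without any downloaded data.

#' Configuration of the synthetic-data generator
#'
#' The defaults mirror the perturbation experiments: 10 trials per worm with
#' 6 s between successive 0.1 s pulses, occasional censored trials, head
#' curvature sampled at 20 Hz with additive white Gaussian observation noise
#' (sd 0.1 in scaled-curvature units), and per-worm lognormal jitter (5%) on
#' the bending time scale and moment amplitude, which translates into
#' frequency and amplitude variability across worms.
#'
#' @param n_worms number of worms.
#' @param trials_per_worm pulses per worm.
#' @param inter_pulse nominal interval between successive pulses (s); each
#'   onset is additionally jittered by up to one cycle so that pulse phases
#'   cover the cycle uniformly.
#' @param noise_sd observation noise sd on K.
#' @param period_jitter lognormal sd of the per-worm `tau_u` factor.
#' @param amplitude_jitter lognormal sd of the per-worm `M0` factor.
#' @param censor_prob probability that a trial is censored.
#' @param sample_rate sampling rate of the emitted recordings (Hz).
#' @param seed integer seed; recorded in all outputs.
#' @param params generating [model_params()].
#' @param spec generating [inhibition_spec()] (its `pulse_duration` is
#'   overridden by `pulse_duration` here).
#' @param pulse_duration pulse duration (s).
#' @param free_duration length of a free-locomotion recording (s).
#' @param pre_window,post_window trial window around each pulse onset (s).
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_worms = 6, trials_per_worm = 10, inter_pulse = 6,
                         noise_sd = 0.1, period_jitter = 0.05,
                         amplitude_jitter = 0.05, censor_prob = 0.05,
                         sample_rate = 20, seed = 1L,
                         params = model_params(), spec = inhibition_spec(),
                         pulse_duration = 0.1, free_duration = 60,
                         pre_window = 4.2, post_window = 4.5) {
  if (censor_prob < 0 || censor_prob > 1) stop("censor_prob must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (sample_rate <= 0 || inter_pulse <= 0) stop("rates and intervals must be positive")
  spec$pulse_duration <- pulse_duration
  structure(list(n_worms = n_worms, trials_per_worm = trials_per_worm,
                 inter_pulse = inter_pulse, noise_sd = noise_sd,
                 period_jitter = period_jitter,
                 amplitude_jitter = amplitude_jitter,
                 censor_prob = censor_prob, sample_rate = sample_rate,
                 seed = as.integer(seed), params = params, spec = spec,
                 pulse_duration = pulse_duration,
                 free_duration = free_duration,
                 pre_window = pre_window, post_window = post_window),
            class = "synth_config")
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$params <- unclass(out$params)
  out$spec <- unclass(out$spec)
  out
}

worm_seed <- function(seed, w) {
  as.integer((as.numeric(seed) * 1000003 + w * 7919) %% 2147483647)
}

jittered_params <- function(cfg) {
  p <- cfg$params
  model_params(tau_u = p$tau_u * exp(rnorm(1, 0, cfg$period_jitter)),
               tau_m = p$tau_m,
               M0 = p$M0 * exp(rnorm(1, 0, cfg$amplitude_jitter)),
               b = p$b, P_th = p$P_th)
}

#' Generate synthetic free-locomotion recordings
#'
#' One continuous pulse-free recording per worm: the threshold-switch model is
#' simulated with per-worm jittered parameters, sampled at `sample_rate`, and
#' white observation noise is added to K. The generating per-worm parameters
#' are returned as ground truth.
#'
#' @param cfg a [synth_config()].
#' @return a `trial_set` whose `truth` holds the generating parameters per
#'   worm; trials have no pulse window.
#' @export
generate_free_recording <- function(cfg) {
  if (!params_oscillatory(cfg$params))
    stop("generating parameters are non-oscillatory")
  trials <- list()
  truth <- list(seed = cfg$seed, params = unclass(cfg$params), worms = list())
  for (w in seq_len(cfg$n_worms)) {
    set.seed(worm_seed(cfg$seed, w))
    pw <- jittered_params(cfg)
    tr <- simulate_free_running(pw, duration = cfg$free_duration + 2,
                                thin = 5L)
    ts <- seq(1, cfg$free_duration + 1, by = 1 / cfg$sample_rate)
    K <- approx(tr$t, tr$K, xout = ts)$y +
      rnorm(length(ts), 0, cfg$noise_sd)
    wid <- sprintf("w%02d", w)
    trials[[wid]] <- trial_record(wid, "free", ts - ts[1], K)
    truth$worms[[wid]] <- list(tau_u = pw$tau_u, tau_m = pw$tau_m,
                               M0 = pw$M0, b = pw$b, P_th = pw$P_th)
  }
  trial_set(trials, truth = truth, config = cfg)
}

#' Generate a synthetic perturbation-trial experiment
#'
#' Emulates the optogenetic PRC experiments: per worm, one continuous
#' recording containing `trials_per_worm` inhibition pulses separated by the
#' nominal `inter_pulse` interval (each onset jittered by up to one cycle so
#' onset phases cover the cycle), sampled at `sample_rate` with observation
#' noise. Each pulse is emitted as one trial window. Ground truth per trial —
#' the true onset phase read off the dense noise-free simulation and the
#' asymptotic phase shift recomputed from a clean single-pulse simulation at
#' that phase — is stored in `truth`.
#'
#' @param cfg a [synth_config()].
#' @return a `trial_set` with pulse windows and a `truth` data frame
#'   (`worm_id, trial_id, phi_true, dphi_true, T0`).
#' @export
generate_prc_experiment <- function(cfg) {
  if (!params_oscillatory(cfg$params))
    stop("generating parameters are non-oscillatory")
  trials <- list()
  rows <- list()
  for (w in seq_len(cfg$n_worms)) {
    set.seed(worm_seed(cfg$seed, w))
    pw <- jittered_params(cfg)
    ref <- oscillator_reference(pw, thin = 5L)
    T0 <- ref$T0
    onsets <- ref$t0 + 2 * T0 + cfg$pre_window +
      (seq_len(cfg$trials_per_worm) - 1) * cfg$inter_pulse +
      runif(cfg$trials_per_worm, 0, T0)
    dur <- max(onsets) + cfg$post_window + 1
    rec <- simulate_free_running(pw, duration = dur, thin = 5L,
                                 spec = cfg$spec, onsets = onsets)
    censored <- runif(cfg$trials_per_worm) < cfg$censor_prob
    # observed recording
    ts <- seq(0, dur, by = 1 / cfg$sample_rate)
    Kobs <- approx(rec$t, rec$K, xout = ts)$y +
      rnorm(length(ts), 0, cfg$noise_sd)
    wid <- sprintf("w%02d", w)
    for (k in seq_len(cfg$trials_per_worm)) {
      # true onset phase from the dense recording: last ventral maximum
      pre <- rec[rec$t >= onsets[k] - 1.6 * T0 & rec$t <= onsets[k], ]
      pk <- dense_maxima(pre$t, pre$K, min_height = -Inf)
      phi_k <- 2 * pi * (onsets[k] - max(pk)) / T0
      pair <- simulate_with_inhibition(pw, cfg$spec, phi_k %% (2 * pi),
                                       reference = ref)
      dphi_k <- asymptotic_phase_shift(pair)
      sel <- ts >= onsets[k] - cfg$pre_window & ts <= onsets[k] + cfg$post_window
      tid <- sprintf("t%02d", k)
      trials[[paste(wid, tid, sep = "_")]] <-
        trial_record(wid, tid, ts[sel], Kobs[sel],
                     pulse_start = onsets[k],
                     pulse_end = onsets[k] + cfg$pulse_duration,
                     side = cfg$spec$side, censored = censored[k])
      rows[[paste(wid, tid, sep = "_")]] <-
        data.frame(worm_id = wid, trial_id = tid,
                   phi_true = phi_k %% (2 * pi), dphi_true = dphi_k, T0 = T0)
    }
  }
  truth <- do.call(rbind, c(rows, make.row.names = FALSE))
  truth$seed <- cfg$seed
  trial_set(trials, truth = truth, config = cfg)
}
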