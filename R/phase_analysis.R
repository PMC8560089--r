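# Phase estimation, PRC construction and phase-portrait estimators for
# curvature time series (experimental or synthetic).

moving_avg <- function(x, window) {
  if (window <= 1) return(x)
  k <- rep(1 / window, window)
  n <- length(x)
  pad <- floor(window / 2)
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(pad + 1):(pad + n)])
}

central_diff <- function(t, x) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  d
}

#' Head curvature from a kymogram
#'
#' Averages a curvature kymogram (body coordinate along columns, time along
#' rows) over a body-coordinate range, by convention 0.1-0.3: the head region,
#' excluding the noisy anterior tip.
#'
#' @param kymogram numeric matrix, rows = time samples, columns = body
#'   coordinates.
#' @param coords body coordinate of each column, in `[0, 1]`.
#' @param range coordinate range to average over.
#' @return numeric vector of head curvature per time sample.
#' @export
head_curvature_from_kymogram <- function(kymogram, coords,
                                         range = c(0.1, 0.3)) {
  if (any(coords < 0 | coords > 1)) stop("body coordinates must be in [0, 1]")
  if (range[1] < 0 || range[2] > 1 || range[1] >= range[2])
    stop("coordinate range must be within [0, 1]")
  sel <- coords >= range[1] & coords <= range[2]
  if (!any(sel)) stop("no kymogram columns inside the coordinate range")
  if (sum(sel) == 1) return(kymogram[, sel])
  rowMeans(kymogram[, sel, drop = FALSE])
}

#' Locate ventral bending maxima in a curvature series
#'
#' Finds local maxima of the (lightly smoothed) curvature above a height
#' fraction of the series maximum, enforces a minimum separation, and refines
#' each peak time by a parabolic fit through the three samples around it.
#'
#' @param t time (s), strictly increasing.
#' @param K curvature series.
#' @param smooth_window moving-average window (samples) applied before peak
#'   detection.
#' @param min_frac minimum peak height as a fraction of the maximum smoothed
#'   curvature.
#' @return numeric vector of refined peak times (s).
#' @export
find_bend_peaks <- function(t, K, smooth_window = 5, min_frac = 0.5) {
  Ks <- moving_avg(K, smooth_window)
  n <- length(Ks)
  if (n < 5) return(numeric(0))
  idx <- which(Ks[2:(n - 1)] >= Ks[1:(n - 2)] & Ks[2:(n - 1)] > Ks[3:n]) + 1L
  idx <- idx[Ks[idx] >= min_frac * max(Ks)]
  if (!length(idx)) return(numeric(0))
  # enforce separation of half the median inter-peak interval, keep higher
  if (length(idx) > 2) {
    min_sep <- 0.5 * median(diff(t[idx]))
    keep <- logical(length(idx))
    ord <- order(Ks[idx], decreasing = TRUE)
    taken <- numeric(0)
    for (i in ord) {
      if (!length(taken) || all(abs(t[idx[i]] - taken) >= min_sep)) {
        keep[i] <- TRUE
        taken <- c(taken, t[idx[i]])
      }
    }
    idx <- sort(idx[keep])
  }
  vapply(idx, function(i) {
    y1 <- Ks[i - 1]; y2 <- Ks[i]; y3 <- Ks[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den < 0) min(max(0.5 * (y1 - y3) / den, -1), 1) else 0
    t[i] + off * mean(diff(t[max(1, i - 1):min(n, i + 1)]))
  }, numeric(1))
}

#' Phase of a curvature series
#'
#' Defines the oscillation phase to be zero at each ventral curvature maximum
#' and to advance linearly in time between consecutive maxima. Before the
#' first and after the last maximum the phase is extrapolated with the
#' neighboring period.
#'
#' @param t time (s).
#' @param K curvature series with at least two detectable ventral maxima.
#' @param peaks optional precomputed peak times (s).
#' @param ... passed to [find_bend_peaks()].
#' @return phase values in `[0, 2pi)` for each time sample, with the peak
#'   times as attribute `peaks`.
#' @export
phase_series <- function(t, K, peaks = NULL, ...) {
  if (is.null(peaks)) peaks <- find_bend_peaks(t, K, ...)
  if (length(peaks) < 2) stop("need at least two ventral maxima")
  k <- length(peaks)
  # unwrapped phase: 2*pi*j at peak j, linear in t between peaks
  phi_u <- approx(peaks, 2 * pi * (seq_len(k) - 1), xout = t, rule = 1)$y
  T_first <- peaks[2] - peaks[1]
  T_last <- peaks[k] - peaks[k - 1]
  before <- t < peaks[1]
  after <- t > peaks[k]
  phi_u[before] <- 2 * pi * (t[before] - peaks[1]) / T_first
  phi_u[after] <- 2 * pi * (k - 1) + 2 * pi * (t[after] - peaks[k]) / T_last
  structure(phi_u %% (2 * pi), peaks = peaks)
}

# per-sample phases relative to a list of peak times (phase 0 at each peak,
# linear within each cycle); returns phases and the sample selector
sample_phases <- function(t, peaks) {
  sel <- t >= peaks[1] & t < peaks[length(peaks)]
  j <- findInterval(t[sel], peaks)
  ph <- (t[sel] - peaks[j]) / (peaks[j + 1L] - peaks[j]) * 2 * pi
  list(sel = sel, phase = ph)
}

#' Cycle-average waveform from a (possibly noisy) curvature series
#'
#' Phase-aligns individual cycles at the ventral maxima (two passes: peak
#' times are refined by template matching against a first-pass average) and
#' fits a truncated Fourier series in phase to all samples jointly. Because
#' sample times fall at different phases in different cycles, the fit has a
#' much finer effective phase resolution than the raw sampling rate, and the
#' curvature derivative comes from differentiating the Fourier series
#' analytically rather than from noisy finite differences.
#'
#' @param t time (s).
#' @param K curvature series spanning at least three cycles.
#' @param n_phase phase-grid resolution of the returned waveform.
#' @param peaks optional precomputed peak times.
#' @param smooth_window smoothing used for peak detection.
#' @param refine refine peak times by template matching (two-pass).
#' @param n_harm number of harmonics of the Fourier fit (capped by the
#'   available samples).
#' @return a `limit_cycle` object (empirical): period, phase grid, `K`,
#'   `Kdot`, amplitude, `U`, `D`, and the waveform standard deviations.
#' @export
cycle_from_series <- function(t, K, n_phase = 128L, peaks = NULL,
                              smooth_window = 5, refine = TRUE,
                              n_harm = 20L) {
  if (is.null(peaks)) peaks <- find_bend_peaks(t, K, smooth_window = smooth_window)
  if (length(peaks) < 4) stop("need at least three full cycles")
  if (refine) {
    # two-pass: align cycles on a first-pass template to remove the
    # peak-timing jitter that smears the average at coarse sampling
    first <- cycle_from_series(t, K, n_phase = n_phase, peaks = peaks,
                               smooth_window = smooth_window, refine = FALSE,
                               n_harm = n_harm)
    peaks <- vapply(peaks, function(pk)
      refine_peak_time(t, K, pk, first$period, first), numeric(1))
  }
  period <- mean(diff(peaks))
  sp <- sample_phases(t, peaks)
  ph <- sp$phase
  y <- K[sp$sel]
  H <- max(3L, min(n_harm, floor(length(y) / 6)))
  X <- matrix(0, length(ph), 2L * H)
  for (h in seq_len(H)) {
    X[, 2L * h - 1L] <- cos(h * ph)
    X[, 2L * h] <- sin(h * ph)
  }
  fit <- lm.fit(cbind(1, X), y)
  cf <- fit$coefficients
  eval_harm <- function(g) {
    Kb <- rep(cf[1], length(g)); Kd <- numeric(length(g))
    for (h in seq_len(H)) {
      a <- cf[2L * h]; b <- cf[2L * h + 1L]
      Kb <- Kb + a * cos(h * g) + b * sin(h * g)
      Kd <- Kd + h * (-a * sin(h * g) + b * cos(h * g))
    }
    list(K = Kb, Kdot = Kd)
  }
  # place phase zero exactly at the fitted waveform's maximum (the raw peak
  # detection that anchored the cycles carries a small systematic offset on
  # asymmetric waveforms)
  fine <- seq(0, 2 * pi, length.out = 513L)[1:512]
  Kf <- eval_harm(fine)$K
  i <- which.max(Kf)
  y1 <- Kf[if (i == 1) 512 else i - 1L]; y2 <- Kf[i]
  y3 <- Kf[if (i == 512) 1L else i + 1L]
  den <- y1 - 2 * y2 + y3
  off <- if (den < 0) min(max(0.5 * (y1 - y3) / den, -0.5), 0.5) else 0
  shift <- fine[i] + off * 2 * pi / 512
  grid <- seq(0, 2 * pi, length.out = n_phase + 1L)[seq_len(n_phase)]
  eh <- eval_harm(grid + shift)
  Kbar <- eh$K
  Kdot <- eh$Kdot * 2 * pi / period
  prod <- Kbar * Kdot
  structure(list(period = period, phase = grid, K = Kbar, Kdot = Kdot,
                 amplitude = max(abs(Kbar)),
                 U = mean(prod > 0), D = mean(prod < 0),
                 sd_K = sd(Kbar), sd_Kdot = sd(Kdot),
                 n_cycles = length(peaks) - 1L, n_harm = H),
            class = "limit_cycle")
}

moving_avg_circular <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  pad <- floor(window / 2)
  xp <- c(tail(x, pad), x, head(x, pad))
  as.numeric(stats::filter(xp, rep(1 / window, window),
                           sides = 2))[(pad + 1):(pad + n)]
}

# radius of the cycle at polar angle theta, in the sd-normalized plane
cycle_radius_fun <- function(cycle) {
  if (cycle$sd_K <= 0 || cycle$sd_Kdot <= 0)
    stop("degenerate cycle: zero variance")
  x <- cycle$K / cycle$sd_K
  y <- cycle$Kdot / cycle$sd_Kdot
  th <- atan2(y, x)
  r <- sqrt(x^2 + y^2)
  o <- order(th)
  th <- th[o]; r <- r[o]
  keep <- c(TRUE, diff(th) > 1e-9)
  th <- th[keep]; r <- r[keep]
  thp <- c(th - 2 * pi, th, th + 2 * pi)
  rp <- rep(r, 3)
  function(theta) approx(thp, rp, xout = theta, rule = 2)$y
}

#' Normalized deviation from the limit cycle
#'
#' Measures how far a state `(K, dK/dt)` lies from the limit cycle in the
#' phase plane with both axes normalized by the cycle's standard deviations.
#' Writing `r` for the state's radial distance and `r_c(theta)` for the
#' cycle's radius at the same polar angle, the deviation is
#' `d = r / r_c(theta) - 1`: `-1` at the origin, `0` on the cycle, positive
#' outside it.
#'
#' @param K,Kdot state coordinates (vectors of equal length).
#' @param cycle a `limit_cycle` (from [extract_limit_cycle()] or
#'   [cycle_from_series()]).
#' @return deviation values, same length as `K`.
#' @export
deviation <- function(K, Kdot, cycle) {
  rc <- cycle_radius_fun(cycle)
  x <- K / cycle$sd_K
  y <- Kdot / cycle$sd_Kdot
  r <- sqrt(x^2 + y^2)
  th <- atan2(y, x)
  r / rc(th) - 1
}

#' Smoothed phase response curve
#'
#' Moving average of per-trial `(phi, dphi)` points along the phase axis with
#' a circular window (default width `0.16 * pi`), with a per-window 95%
#' t-interval.
#'
#' @param points a `prc_points` data frame (columns `phi`, `dphi`).
#' @param bin_width window width (rad).
#' @param grid phase grid on which to evaluate the moving average.
#' @param level confidence level.
#' @param min_pts windows with fewer points are flagged (`ok = FALSE`) and
#'   their CI set to `NA`.
#' @return an object of class `smoothed_prc`: data frame with `phi`, `dphi`,
#'   `ci`, `n`, `ok`.
#' @export
smooth_prc <- function(points, bin_width = 0.16 * pi,
                       grid = seq(0, 2 * pi, length.out = 65L)[1:64],
                       level = 0.95, min_pts = 3L) {
  if (nrow(points) == 0) stop("empty PRC point set")
  phi <- points$phi %% (2 * pi)
  dphi <- points$dphi
  out <- lapply(grid, function(g) {
    d <- abs(wrap_pi(phi - g))
    sel <- d <= bin_width / 2
    n <- sum(sel)
    if (n == 0) return(c(NA_real_, NA_real_, 0))
    m <- mean(dphi[sel])
    ci <- if (n >= max(2L, min_pts)) {
      qt(1 - (1 - level) / 2, n - 1) * sd(dphi[sel]) / sqrt(n)
    } else NA_real_
    c(m, ci, n)
  })
  out <- do.call(rbind, out)
  structure(data.frame(phi = grid, dphi = out[, 1], ci = out[, 2],
                       n = as.integer(out[, 3]),
                       ok = out[, 3] >= min_pts),
            bin_width = bin_width,
            class = c("smoothed_prc", "data.frame"))
}

#' @export
plot.smoothed_prc <- function(x, ...) {
  plot(x$phi, x$dphi, type = "l", xlab = "inhibition phase (rad)",
       ylab = "phase shift (rad, + = delay)", ...)
  ok <- x$ok & !is.na(x$ci)
  if (any(ok))
    polygon(c(x$phi[ok], rev(x$phi[ok])),
            c(x$dphi[ok] + x$ci[ok], rev(x$dphi[ok] - x$ci[ok])),
            col = adjustcolor("steelblue", 0.3), border = NA)
  abline(h = 0, col = "grey70")
  invisible(x)
}

#' Two-dimensional histogram of PRC points
#'
#' Bins the `(phi, dphi)` point cloud on a square grid (default 25 x 25).
#' Useful to distinguish genuinely abrupt (bimodal) transitions from
#' continuous ones that only look abrupt after averaging.
#'
#' @param points a `prc_points` data frame.
#' @param bins number of bins per dimension.
#' @return a list with the count matrix (`phi` along rows) and the bin edges.
#' @export
prc_hist2d <- function(points, bins = 25L) {
  if (nrow(points) == 0) stop("empty PRC point set")
  phi_br <- seq(0, 2 * pi, length.out = bins + 1L)
  rng <- range(points$dphi)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  dphi_br <- seq(rng[1], rng[2], length.out = bins + 1L)
  ip <- pmin(pmax(findInterval(points$phi %% (2 * pi), phi_br,
                               rightmost.closed = TRUE), 1L), bins)
  id <- pmin(pmax(findInterval(points$dphi, dphi_br,
                               rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  for (i in seq_along(ip)) counts[ip[i], id[i]] <- counts[ip[i], id[i]] + 1L
  list(counts = counts, phi_breaks = phi_br, dphi_breaks = dphi_br)
}

# Fit the two-line structure of (Ma, dMa/dt): if Ma relaxes first-order
# toward alternating targets +/-M0, the points lie on two lines of common
# slope -1/tau_m and intercepts +/-M0/tau_m. Samples are assigned to the
# better-fitting line (a few EM-style reassignment rounds), which handles the
# ambiguous near-plateau region where dMa ~ 0.
fit_moment_lines <- function(Ma, dMa, n_em = 4L) {
  lab <- ifelse(dMa > 0, 1L, -1L)
  fits <- NULL
  for (it in seq_len(n_em)) {
    fits <- lapply(c(1, -1), function(s) {
      sel <- lab == s
      if (sum(sel) < 5) return(NULL)
      lm(dMa[sel] ~ Ma[sel])
    })
    if (any(vapply(fits, is.null, logical(1)))) return(NULL)
    pred <- vapply(fits, function(f)
      coef(f)[1] + coef(f)[2] * Ma, numeric(length(Ma)))
    res2 <- (dMa - pred)^2
    lab <- ifelse(res2[, 1] <= res2[, 2], 1L, -1L)
    r2 <- pmin(res2[, 1], res2[, 2])
    # trim the few samples whose centered difference straddles a switch:
    # there dMa genuinely jumps between the two lines and fits neither
    ss <- mean(r2[r2 <= quantile(r2, 0.95)])
  }
  slopes <- vapply(fits, function(f) unname(coef(f)[2]), numeric(1))
  ints <- vapply(fits, function(f) unname(coef(f)[1]), numeric(1))
  if (any(slopes >= 0)) return(NULL)
  list(ss = ss, tau_m = mean(-1 / slopes),
       M0 = mean(abs(ints / slopes)), labels = lab)
}

#' Estimate the bending relaxation time scale from a curvature series
#'
#' Exploits the structure of the curvature equation: the implied active
#' moment `Ma = K + tau K'` is, at the true `tau = tau_u`, exactly a
#' first-order relaxation toward alternating saturation levels, so the points
#' `(Ma, dMa/dt)` collapse onto two straight lines (common slope `-1/tau_m`,
#' intercepts `+/- M0/tau_m`). The default estimator (`method =
#' "linearity"`) minimizes the two-line misfit over `tau`. For sampled or
#' noisy data the series is first reduced to its cycle-average waveform,
#' whose effective noise is negligible.
#'
#' For sampled or noisy recordings (`average = TRUE`, the default when the
#' series spans several cycles) the series is first reduced to its
#' cycle-average waveform and the default method becomes `"waveform"`: a
#' least-squares fit of the oscillator's own waveform family
#' ([fit_waveform_params()]), which is robust to the finite phase resolution
#' that blurs the moment transitions and biases derivative-based estimators.
#'
#' `method = "plateau"` instead regresses `dK/dt` on `K` over the plateau
#' segments (where `|dMa/dt|` is below `plateau_frac` of its maximum) and
#' returns `-1/slope` averaged over the two branches, iterated to
#' self-consistency. This simpler reading of the phase portrait's "nearly
#' linear portions" is biased upward when the muscle time constant is not
#' small compared to the plateau (the moment's exponential tail tilts the
#' regression), and is provided for comparison.
#'
#' @param t time (s).
#' @param K curvature series.
#' @param Kdot optional curvature derivative; computed by smoothed centered
#'   differences when missing.
#' @param average cycle-average before estimating (recommended for sampled or
#'   noisy data). Default: average whenever the series spans > 4 cycles.
#' @param method `"auto"` (default: `"waveform"` when averaging,
#'   `"linearity"` otherwise), `"linearity"`, `"waveform"` or `"plateau"`.
#' @param plateau_frac threshold for the plateau method.
#' @param n_iter fixed-point iterations (plateau method).
#' @param smooth_window smoothing window (samples) for derivative estimation.
#' @return estimated `tau_u` (s); the linearity and waveform methods attach
#'   attributes `tau_m` and `M0` (byproducts of the fit), the plateau method
#'   attribute `branches`.
#' @export
estimate_tau_u <- function(t, K, Kdot = NULL, average = NULL,
                           method = c("auto", "linearity", "waveform",
                                      "plateau"),
                           plateau_frac = 0.2, n_iter = 6L,
                           smooth_window = 5) {
  method <- match.arg(method)
  if (is.null(average)) {
    pk <- tryCatch(find_bend_peaks(t, K, smooth_window = smooth_window),
                   error = function(e) numeric(0))
    average <- length(pk) > 5
  }
  if (method == "auto") method <- if (average) "waveform" else "linearity"
  if (method == "waveform") {
    cyc <- if (average) cycle_from_series(t, K, smooth_window = smooth_window)
           else stop("waveform method requires average = TRUE")
    f <- fit_waveform_params(cyc)
    return(structure(f$tau_u, tau_m = f$tau_m, M0 = f$M0, K_sw = f$K_sw,
                     mse = f$mse))
  }
  if (average) {
    cyc <- cycle_from_series(t, K, smooth_window = smooth_window)
    # unroll two periods so transitions never sit at an array edge
    tt <- c(cyc$phase, cyc$phase + 2 * pi) / (2 * pi) * cyc$period
    KK <- rep(cyc$K, 2)
    KD <- rep(cyc$Kdot, 2)
    period <- cyc$period
  } else {
    tt <- t
    if (is.null(Kdot)) {
      KK <- moving_avg(K, smooth_window)
      KD <- central_diff(tt, KK)
    } else {
      KK <- K
      KD <- Kdot
    }
    pk <- tryCatch(find_bend_peaks(tt, KK, smooth_window = 1),
                   error = function(e) numeric(0))
    period <- if (length(pk) >= 3) median(diff(pk)) else diff(range(tt)) / 5
  }

  if (method == "linearity") {
    obj <- function(tau) {
      f <- fit_moment_lines(KK + tau * KD, central_diff(tt, KK + tau * KD))
      if (is.null(f)) return(1e12)
      f$ss
    }
    # The objective has two exact minima: tau = tau_u isolates the muscle
    # mode (what we want) and tau = tau_m isolates the bending mode (a
    # pseudo-moment that is also piecewise first-order). Scan, polish each
    # candidate basin, and keep the one whose implied moment actually
    # saturates: the true moment sits on its plateaus for most of the cycle,
    # the pseudo-moment never reaches them.
    taus <- exp(seq(log(period / 60), log(period), length.out = 40L))
    vals <- vapply(taus, obj, numeric(1))
    loc <- which(diff(sign(diff(vals))) > 0) + 1L
    if (!length(loc)) loc <- which.min(vals)
    loc <- loc[order(vals[loc])][seq_len(min(2L, length(loc)))]
    cand <- lapply(loc, function(i) {
      lo <- taus[max(1L, i - 1L)]; hi <- taus[min(length(taus), i + 1L)]
      op <- optimize(obj, interval = c(lo, hi), tol = 1e-4 * period)
      tau <- op$minimum
      f <- fit_moment_lines(KK + tau * KD, central_diff(tt, KK + tau * KD))
      if (is.null(f)) return(NULL)
      Ma <- KK + tau * KD
      f$sat <- mean(abs(Ma) > 0.85 * f$M0)
      f$tau <- tau
      f
    })
    cand <- Filter(Negate(is.null), cand)
    if (!length(cand)) stop("two-line moment fit failed")
    best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "sat"))]]
    return(structure(best$tau, tau_m = best$tau_m, M0 = best$M0,
                     saturation = best$sat))
  }

  tau <- period / 4
  branches <- c(NA_real_, NA_real_)
  for (it in seq_len(n_iter)) {
    Ma <- KK + tau * KD
    dMa <- central_diff(tt, Ma)
    thr <- plateau_frac * quantile(abs(dMa), 0.98)
    plateau <- abs(dMa) < thr
    sl <- vapply(c(1, -1), function(s) {
      sel <- plateau & (sign(Ma) == s)
      if (sum(sel) < 5) return(NA_real_)
      unname(coef(lm(KD[sel] ~ KK[sel]))[2])
    }, numeric(1))
    branches <- -1 / sl
    new_tau <- mean(branches, na.rm = TRUE)
    if (!is.finite(new_tau) || new_tau <= 0)
      stop("no usable plateau segment found")
    if (abs(new_tau - tau) < 1e-5 * tau) { tau <- new_tau; break }
    tau <- new_tau
  }
  structure(tau, branches = branches)
}

#' Active-moment series from curvature
#'
#' Pointwise reconstruction of the scaled active muscle moment from the
#' curvature equation: `Ma = K + tau_u * dK/dt`.
#'
#' @param K curvature.
#' @param Kdot curvature time derivative (same length).
#' @param tau_u bending relaxation time scale (s).
#' @return the moment series.
#' @export
estimate_moment_series <- function(K, Kdot, tau_u) {
  if (length(K) != length(Kdot)) stop("K and Kdot must have equal length")
  if (tau_u <= 0) stop("tau_u must be positive")
  K + tau_u * Kdot
}

#' Estimate the muscle switching time scale from a moment series
#'
#' The reconstructed active moment alternates between two plateaus with rapid
#' transitions. For a first-order step response the maximum slope during a
#' transition equals (plateau difference) / `tau_m`, so
#' `tau_m = dM / max |dMa/dt|`, averaged over transitions.
#'
#' @param t time (s).
#' @param Ma active-moment series (for sampled data, from the cycle-average
#'   waveform; see [estimate_tau_u()]).
#' @param plateau_frac threshold defining plateau samples.
#' @return estimated `tau_m` (s), with per-transition estimates as attribute
#'   `transitions`.
#' @export
estimate_tau_m <- function(t, Ma, plateau_frac = 0.2) {
  dMa <- central_diff(t, Ma)
  thr <- plateau_frac * quantile(abs(dMa), 0.98)
  plateau <- abs(dMa) < thr
  lev_hi <- plateau_level(Ma[plateau & Ma > 0])
  lev_lo <- -plateau_level(-Ma[plateau & Ma < 0])
  if (!is.finite(lev_hi) || !is.finite(lev_lo))
    stop("could not identify two moment plateaus")
  dM <- lev_hi - lev_lo
  # transition runs = maximal stretches of non-plateau samples
  r <- rle(!plateau)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trans <- which(r$values & r$lengths >= 2)
  if (length(trans) < 2) stop("need at least two plateau-to-plateau transitions")
  taus <- vapply(trans, function(j) {
    seg <- starts[j]:ends[j]
    dM / max(abs(dMa[seg]))
  }, numeric(1))
  structure(mean(taus), transitions = taus)
}

# saturation level of a one-sided plateau sample set: the upper quartile,
# which for a first-order approach to saturation sits within a fraction of a
# percent of the asymptote, where the plain mean is biased low by the early
# part of the approach
plateau_level <- function(x) {
  if (!length(x)) return(NA_real_)
  unname(quantile(x, 0.75))
}

#' Locate the sawtooth jump phases of a PRC point cloud
#'
#' The biphasic PRC consists of two linearly rising teeth separated by two
#' abrupt downward jumps half a cycle apart. This estimator scans the phase
#' of the first jump `J` over `[0, pi)`, splits the points into the two
#' teeth `(J, J + pi)` and `(J + pi, J + 2 pi)`, fits a line per tooth, and
#' returns the `J` minimizing the total squared residual (with parabolic
#' refinement). Because individual points on either side of a jump differ by
#' the whole tooth height, this localizes the jumps far more precisely than
#' any binned average.
#'
#' When the points carry a per-trial period (column `T0`) and the time of
#' peak suppression `t_c` is supplied, each point's phase is first corrected
#' for its worm's period (jump phases scale like `t_c / T0`), which unblurs
#' the pooled jump.
#'
#' @param points a `prc_points` data frame.
#' @param t_c time from pulse onset to peak suppression (s), for the
#'   per-worm period correction.
#' @param n_scan scan resolution over `[0, pi)`.
#' @return jump phase `J` in `[0, pi)` (the second jump is at `J + pi`),
#'   with the scan profile as attribute `sse`.
#' @export
estimate_prc_jumps <- function(points, t_c = NULL, n_scan = 120L) {
  phi <- points$phi
  if (!is.null(points$T0) && !is.null(t_c)) {
    T0 <- points$T0
    phi <- phi + 2 * pi * t_c * (1 / T0 - 1 / median(T0))
  }
  phi <- phi %% (2 * pi)
  dphi <- points$dphi
  if (length(phi) < 10) stop("need at least 10 PRC points")
  Js <- seq(0, pi, length.out = n_scan + 1L)[seq_len(n_scan)]
  sse <- vapply(Js, function(J) {
    x <- (phi - J) %% (2 * pi)
    s <- 0
    for (k in 1:2) {
      sel <- if (k == 1) x < pi else x >= pi
      if (sum(sel) >= 3) {
        f <- lm.fit(cbind(1, x[sel]), dphi[sel])
        s <- s + sum(f$residuals^2)
      } else s <- s + sum(dphi[sel]^2)
    }
    s
  }, numeric(1))
  i <- which.min(sse)
  J <- Js[i]
  i1 <- if (i == 1) n_scan else i - 1L
  i3 <- if (i == n_scan) 1L else i + 1L
  den <- sse[i1] - 2 * sse[i] + sse[i3]
  if (den > 0)
    J <- J + 0.5 * (sse[i1] - sse[i3]) / den * (pi / n_scan)
  structure(J %% pi, sse = data.frame(J = Js, sse = sse))
}
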