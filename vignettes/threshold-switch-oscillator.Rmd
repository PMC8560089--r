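---
title: "A proprioceptive threshold-switch oscillator for C. elegans head undulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A proprioceptive threshold-switch oscillator for C. elegans head undulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(undulator)
```

## The model

During forward locomotion, *C. elegans* bends its head rhythmically at about
1 Hz (in a medium of roughly 120 mPa·s). `undulator` implements a compact
phenomenological model of how this rhythm is generated: a relaxation
oscillator built from a biomechanical bending equation and a proprioceptive
switching rule.

The head segment is treated as a viscoelastic rod whose dimensionless scaled
curvature $K = \kappa L$ (positive = ventral bend) obeys

$$K(t) + \tau_u \dot K(t) = M_a(t),$$

where $\tau_u$ is the bending relaxation time scale — the time the body
takes, against external drag and internal viscoelasticity, to approach the
static curvature set by the muscles — and $M_a$ is the scaled active muscle
moment. The muscles themselves relax with a time constant $\tau_m$ toward a
target moment that takes one of two values:

$$\tau_m \dot M_a = M_t - M_a, \qquad M_t \in \{+M_0, -M_0\}.$$

The rhythm comes from proprioception: the sensed posture signal
$P = K + b\dot K$ (curvature plus a weighted curvature rate) flips the
target from ventral-driving to dorsal-driving when it crosses $+P_{th}$
upward, and back when it crosses $-P_{th}$ downward. The switching is
hysteretic, so there is no chattering: after a flip the signal must travel
to the *opposite* threshold before the next flip.

Five parameters fully specify the model. The package defaults are the
values estimated for worms at the reference viscosity, with $M_0$
calibrated so that each muscle-moment plateau lasts about half a second:

| parameter | meaning | default | unit |
|---|---|---|---|
| `tau_u` | bending relaxation time | 0.26 | s |
| `tau_m` | muscle switching time | 0.10 | s |
| `M0`    | moment amplitude | 3.5 | — |
| `b`     | proprioceptive velocity weight | 0.046 | s |
| `P_th`  | proprioceptive threshold | 2.33 | — |

```{r free-run}
params <- model_params()
traj <- simulate_free_running(params, duration = 20, thin = 10L)
cycle <- extract_limit_cycle(traj)
cycle
```

Because the moment saturates quickly ($\tau_m \ll$ half-period), the
curvature relaxes exponentially toward $\mp M_0$ during most of each
half-cycle and the oscillation is strongly nonsinusoidal: bending toward
the ventral or dorsal side (the fraction `U` of the cycle) takes visibly
longer than straightening (`D`), because the relaxation toward the far
moment is fastest right after a switch.

```{r portrait, fig.show = "hold"}
op <- par(mfrow = c(1, 2))
plot(traj[traj$t > 14 & traj$t < 18, ], main = "waveform")
plot(cycle, main = "phase portrait")
par(op)
```

### Numerical scheme

The muscle equation is linear and independent of $K$, so between switches
it is advanced *exactly* (exponential update); this keeps the integrator
stable even in the instantaneous-muscle limit $\tau_m \to 0$. The curvature
is advanced by classical fixed-step RK4 (default $\Delta t$ = 0.5 ms)
against the analytic $M_a(t)$. Threshold crossings are located by linear
interpolation of $P$ within a step and the switch is applied at the
interpolated time; a value landing exactly on a threshold counts as a
crossing. In the limit $b = 0$, $\tau_m \to 0$ the period has the closed
form

$$T = 2\tau_u \log\frac{M_0 + K_{sw}}{M_0 - K_{sw}},
\qquad K_{sw} = \frac{P_{th} - (b/\tau_u) M_0}{1 - b/\tau_u},$$

which the simulator reproduces to better than 0.1%; halving the step
changes the period by less than 0.1%.

```{r oracle}
p0 <- model_params(tau_u = 0.26, tau_m = 1e-4, M0 = 3.0, b = 0, P_th = 2.33)
ev <- switch_events(simulate_free_running(p0, duration = 12, thin = 10L))
c(closed_form = period_tau_m_zero(p0),
  simulated = mean(diff(ev$t[ev$sign == 1 & ev$t > 4])))
```

## Transient muscle inhibition and the phase response curve

Optogenetic silencing of the body-wall muscles transiently removes the
active moment and the head straightens. The package models the paralysis as
a bell-shaped (Gaussian) suppression of the moment entering the curvature
equation, $M_a (1 - \varepsilon(t))$ with
$\varepsilon(t) = \text{depth}\cdot
\exp(-(t - t_{on} - \text{peak\_delay})^2 / 2\,\text{width}^2)$, truncated
beyond five widths. The target-moment state machine keeps running during
the pulse — paralysis is muscular, not neural. For single-side illumination
the suppression applies only while the illuminated side's muscles drive the
bend (gated on the sign of $M_a$), with a weaker default depth on the
dorsal side.

The envelope's exact physiological shape is not observable directly; its
`peak_delay` and `width` defaults (0.42 s and 0.04 s) were calibrated once
against two behavioral anchors and are not data-fitted per run:

* the head is maximally paralyzed about 0.3 s after the light pulse ends;
* the phase response curve's abrupt transitions sit near $\pi/3$ and
  $4\pi/3$.

```{r paralysis}
spec <- inhibition_spec()
pt <- paralysis_timing(params, spec, n_phases = 12L)
pt$t_min  # seconds from pulse end to maximal paralysis
```

Paralysis depth is quantified with the normalized deviation $d$: in the
phase plane with both axes scaled by the cycle's standard deviations,
$d = r/r_c(\theta) - 1$, where $r_c(\theta)$ is the cycle's radius at the
state's polar angle. By construction $d = -1$ at the origin (straight
posture), $d = 0$ on the limit cycle and $d > 0$ outside it. Unlike
$|K|$ itself, $d$ does not oscillate over the cycle, so paralysis profiles
can be averaged across pulses delivered at all phases without interference
from the pulse-induced phase resetting.

The *phase response curve* (PRC) gives the asymptotic phase shift caused by
a pulse as a function of the phase at which it was delivered (phase zero at
the ventral curvature maximum; delays positive). Shifts are measured by
comparing the timing of late switch events — at least five cycles after the
pulse — between the perturbed trajectory and an unperturbed reference with
identical history.

```{r prc}
prc <- model_prc(params, spec, n_phases = 64L)
plot(prc, pch = 16, cex = 0.6)
prc_transition_phases(prc)
```

The PRC is a biphasic sawtooth: two linearly rising teeth of delay,
terminated by two abrupt downward jumps half a cycle apart. The mechanism
is geometric: a pulse whose paralysis arrives shortly *before* a switch
point lets the bend sag and forces it to be rebuilt, postponing the next
switch (a delay that grows the closer the pulse is to the switch); once the
paralysis arrives just *after* the switch, the bend is aborted instead and
the shift collapses. With the multiplicative moment suppression used here
the collapsed branch sits near zero rather than clearly negative: during
suppression the curvature relaxes toward zero at rate $K/\tau_u$, which is
*slower* than normal straightening toward $-M_0$, so the time gained by
aborting the bend is mostly spent paralyzed. A sizable phase advance would
require a suppression mechanism that actively accelerates straightening;
the experimental advance is small, and reproducing its exact depth is a
known limitation of this envelope choice.

## Estimating the parameters from curvature recordings

### Direct estimates: $\tau_u$, $\tau_m$, $M_0$

All estimators work on the cycle-average waveform: individual cycles are
aligned at the ventral maxima (with template-matching refinement of the
peak times) and a truncated Fourier series in phase is fitted to all
samples jointly (`cycle_from_series()`). Because samples fall at different
phases in different cycles, the effective phase resolution is far finer
than the raw sampling rate, and derivatives come from differentiating the
Fourier series analytically.

For dense, noise-free series `estimate_tau_u()` uses a structural
identity: the implied moment $K + \tau \dot K$ is exactly a first-order
relaxation toward alternating saturation levels *if and only if*
$\tau = \tau_u$, in which case the points $(M_a, \dot M_a)$ collapse onto
two straight lines with common slope $-1/\tau_m$ and intercepts
$\pm M_0/\tau_m$. Minimizing the two-line misfit over $\tau$ therefore
recovers $\tau_u$, with $\tau_m$ and $M_0$ as byproducts. The objective has
a second exact minimum at $\tau = \tau_m$ (the complementary eigenmode is
also piecewise first-order); the ambiguity is resolved physically — the
true moment *saturates*, spending most of the cycle on its plateaus, while
the swapped assignment's pseudo-moment never reaches them.

A simpler reading of the phase portrait — regressing $\dot K$ on $K$ over
the "plateau" samples where $|\dot M_a|$ is small — is available as
`method = "plateau"`, but it is biased upward whenever $\tau_m$ is not
negligible relative to the half-period: the moment's exponential tail tilts
the regression. At the fitted parameters the bias exceeds 70%, which is why
it is not the default.

For sampled, noisy recordings the default is a least-squares fit of the
model's own waveform family to the cycle average
(`fit_waveform_params()`). Two structural facts shape this fit:

* the free-running waveform depends on $(b, P_{th})$ only through the
  switch curvature $K_{sw}$ (between switches the dynamics contain neither,
  and at the switch the moment has long saturated), so the family is
  parameterized by $(\tau_u, \tau_m, M_0, K_{sw})$ with $b = 0$;
* the waveform is exactly invariant under exchanging $\tau_u$ and $\tau_m$
  — two first-order filters in series commute — so the fit determines the
  pair and the labels are assigned by the saturation test above.

```{r fit-direct}
cfg <- synth_config(n_worms = 2, seed = 1, free_duration = 40)
free <- generate_free_recording(cfg)
fit_direct(free)[c("tau_u", "tau_m", "M0", "K_sw")]
```

### The two-round fit: $b$ and $P_{th}$

Round 1 fits $(b, P_{th})$ to the free-moving cycle waveform by grid search
plus a local polish. Because of the ridge described above, round 1 really
pins $K_{sw}$ (to a fraction of a percent) and leaves $(b, P_{th})$
anywhere along it. Round 2 turns to the PRC, which does discriminate along
the ridge: during a pulse the moment deficit makes the switch condition
genuinely $b$-sensitive, and the signature is the *phase of the sawtooth
jumps* (sensitivity roughly 3 rad per unit of $b$).

The jump phases, however, respond equally to the suppression envelope's
timing (about $-2\pi/T_0$ rad per second of peak delay, and more steeply to
its width), so $b$ is identifiable only when the envelope's temporal
profile is known independently — in the synthetic-data setting it is
treated as a known property of the perturbation apparatus, and the
empirical paralysis-dip lag (`paralysis_lag_from_trials()`,
`calibrate_peak_delay()`) provides a data-driven check of the peak delay.
Given the timing, the staged round-2 estimator (i) fits the suppression
depth, (ii) localizes the empirical jumps by change-point regression over
the raw per-trial points — individual points on either side of a jump
differ by the whole tooth height, so this is far sharper than any binned
average — with each point's phase corrected for its worm's measured period,
and (iii) solves for $b$ so that the model's jump (found by bisection)
matches, with $P_{th}$ tied to the round-1 $K_{sw}$. Even so, $b$ remains
the least determined parameter: percent-level errors anywhere upstream move
the predicted jump by as much as a 20–30% change in $b$, and recovery
experiments at a few hundred trials should be read with that in mind.
$P_{th}$, dominated by the waveform-pinned $K_{sw}$, is recovered to a few
percent.

`parameter_recovery_experiment()` packages the whole loop — generate
synthetic data, estimate, tabulate true versus recovered — across
replicates and noise levels. Its defaults (4 free-moving worms of 50 s and
20 pulse worms with 10 trials each per replicate) are a realistic
desk-scale subset of the data volumes behind the original estimates.

## The synthetic-data generator

`generate_free_recording()` and `generate_prc_experiment()` emulate the
behavioral experiments with exact ground truth: per-worm lognormal jitter
(5%) on $\tau_u$ and $M_0$ (frequency and amplitude variability), head
curvature sampled at 20 Hz with additive white Gaussian observation noise
(sd 0.1 in scaled-curvature units), 10 pulses per worm nominally 6 s apart,
and occasional censored trials. Pulse onsets are jittered by up to one
cycle so that onset phases cover the cycle approximately uniformly — with
strictly fixed spacing the deterministic model would sample phases on a
rigid lattice. Ground truth per pulse (true onset phase and asymptotic
shift) is recomputed from clean single-pulse simulations, which is exact
because the settled deterministic oscillator is memoryless.

What the generator does *not* emulate: tracking artifacts and outliers,
non-Gaussian or temporally correlated measurement noise, within-worm
drift of period or amplitude, reversals and pauses (censoring is random
rather than behavior-driven), and any body-coordinate structure beyond the
head average. Passing recovery tests on this generator therefore validates
the estimation machinery, not robustness to every artifact of real
recordings.

## Gait adaptation to viscosity

External load enters through the bending relaxation time:
`tau_u_of_eta()` maps viscosity $\eta$ affinely to $\tau_u$, anchored at
0.26 s for 120 mPa·s. The default keeps an internal-damping intercept of
0.15 s: a strictly proportional map would drive $\tau_u$ below $b$ in
watery media (destroying the oscillation — the posture signal would be
dominated by its velocity term), whereas with the intercept the model swims
at about 2 Hz in water and slows monotonically as the load grows. The
intercept is a configuration choice, not a fitted constant; the linear
form itself extrapolates poorly to extreme viscosities, where the model
undulates more slowly than real crawling worms.

```{r gait}
gait_scan(c(10, 120, 5400))[, c("eta", "tau_u", "frequency_hz", "amplitude")]
```

Frequency falls and amplitude grows with load, and the mechanism is
visible in the scan's extra columns: at the switch point the velocity share
$|b\dot K|$ of the proprioceptive signal shrinks with load, so the worm
must bend further ($|K|$ at the switch grows) before the threshold trips.
The PRC's sawtooth transitions also shift to later phases as viscosity
increases (`prc_viscosity_scan()`), because the paralysis occupies a
smaller fraction of a longer cycle.

## Alternative oscillators

Three classical oscillators are provided under the same perturbation/PRC
interface for comparison, each rescaled in time and amplitude to the data:
van der Pol ($\ddot x - \mu(1 - x^2)\dot x + x = 0$), Rayleigh
($\ddot x - \mu(1 - \dot x^2)\dot x + x = 0$, the derivative of a van der
Pol solution), and Stuart-Landau
($\dot z = (\lambda + i\omega - |z|^2)z$). The muscle-inhibition analog
suppresses each system's *active drive*: the nonlinear velocity-dependent
damping term (the energy source) for van der Pol and Rayleigh, and a
radial contraction for Stuart-Landau, whose rotation has no such term.
With $\mu = 5$ the two relaxation oscillators are strongly nonsinusoidal
and produce sawtooth-shaped PRCs; the van der Pol waveform's slow/fast
asymmetry is inverted relative to the threshold-switch model's. The
Stuart-Landau oscillator is sinusoidal and — because its radial direction
carries no phase information — has a PRC that is constant in phase, unlike
the experiments. `model_comparison_report()` scores all four models
against a target waveform and PRC; against threshold-model-generated
targets the threshold-switch model attains the lowest mean squared errors.

## Numerical and design notes

* Phases live in $[0, 2\pi)$, shifts in $(-\pi, \pi]$ with ties at
  $-\pi$ resolved to $+\pi$; delays are positive throughout.
* Smoothed PRCs use a circular moving average of width $0.16\pi$ with a
  per-window t-interval; windows with fewer than 3 points are flagged.
* Per-trial phase shifts extrapolate the pre-pulse rhythm by linear
  regression of refined peak times; recovery is declared when the
  normalized deviation stays below a threshold (calibrated against the
  trial's own pre-pulse deviation, which absorbs smoothing bias) for most
  of a full cycle.
* Transient discard for cycle extraction is the larger of 20% of the
  trajectory and five full cycles; periods are measured between every
  second switch event.
* Simulation sizes in the examples and tests (tens of seconds at
  $\Delta t$ = 0.5 ms, a few worms, a few dozen trials) were chosen as the
  smallest sets on which the estimators' behavior is representative.
* The deposited experimental dataset is not bundled; all analyses here run
  on synthetic data with known ground truth, and the functions accept real
  head-curvature recordings in the same trial format.
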