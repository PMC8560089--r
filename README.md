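# undulator

Rhythmic forward locomotion in *C. elegans* — head bending at roughly 1 Hz
in a viscous medium — can be generated without a dedicated neural pacemaker:
a body segment that senses its own posture and switches its muscles when a
proprioceptive threshold is reached behaves as a relaxation oscillator.
`undulator` implements that model and the analysis pipeline around it, for
researchers studying locomotor rhythm generation, phase response analysis of
behavioral oscillators, or neuromechanical models of undulatory gaits.

The core is a five-parameter threshold-switch oscillator. The scaled
curvature K = κ·L of the head segment follows a viscoelastic bending
equation

    K + tau_u dK/dt = Ma,         tau_m dMa/dt = Mt - Ma,

where the active muscle moment Ma relaxes toward a target moment
Mt ∈ {+M0, −M0}, and the proprioceptive signal P = K + b·dK/dt flips the
target at thresholds ±P_th (hysteretically: +P_th crossed upward switches to
dorsal drive, −P_th crossed downward back to ventral). Defaults are the
values estimated at 120 mPa·s: tau_u = 0.26 s, tau_m = 0.1 s, b = 0.046 s,
P_th = 2.33, with M0 = 3.5 calibrated so the moment plateaus last ~0.5 s.

Around the model, the package provides:

* transient optogenetic muscle-inhibition simulations (bilateral and
  single-side) with a bell-shaped suppression envelope, and model phase
  response curves (PRCs) — a sawtooth with two abrupt delay-to-advance
  transitions near π/3 and 4π/3;
* the empirical pipeline: per-trial inhibition phase and phase shift from
  head-curvature recordings, moving-average PRC smoothing, 2-D PRC
  histograms, and the normalized deviation d from the limit cycle
  (−1 at the straight posture, 0 on the cycle);
* phase-portrait estimators of tau_u, tau_m and M0, and a two-round fit of
  (b, P_th): waveform first, PRC second;
* gait adaptation to external viscosity through tau_u (frequency falls,
  amplitude grows, PRC transitions shift rightward);
* van der Pol, Rayleigh and Stuart-Landau oscillators under the same
  perturbation interface, with a model-comparison report;
* a synthetic-data generator emulating the perturbation experiments
  (10 trials/worm at ~6 s spacing, 20 Hz sampling, observation noise,
  per-worm variability, censoring) with exact ground truth.

## Worked example

```r
library(undulator)

params <- model_params()          # fitted parameters at 120 mPa s
traj <- simulate_free_running(params, duration = 30, thin = 5L)
extract_limit_cycle(traj)
#> Limit cycle: period 1.004 s, amplitude 2.141, U = 0.547, D = 0.453 (23 cycles averaged)
```

The period is ~1 s and the cycle is asymmetric: bending (`U`, 55% of the
cycle) is slower than straightening (`D`, 45%), the signature of relaxation
toward a saturated muscle moment. Switch events give the moment plateau
duration directly:

```r
ev <- switch_events(traj)
mean(ev$plateau[ev$t > 6], na.rm = TRUE)
#> [1] 0.5021
```

A 0.1 s bilateral muscle inhibition delivered across all phases yields the
sawtooth PRC and the timing of maximal paralysis:

```r
spec <- inhibition_spec()
prc <- model_prc(params, spec, n_phases = 64L)
prc_transition_phases(prc)     # abrupt delay-to-advance transitions (rad)
#> [1] 1.030835 4.172428        # near pi/3 = 1.047 and 4*pi/3 = 4.189

paralysis_timing(params, spec, n_phases = 12L)$t_min
#> [1] 0.3362                   # s after pulse end; observed: ~0.3 s
```

The full synthetic loop — generate pulse trials, measure per-trial phase
shifts, smooth — takes a few lines:

```r
cfg <- synth_config(n_worms = 4, seed = 1)
trials <- generate_prc_experiment(cfg)
pts <- analyze_trials(trials)
sm <- smooth_prc(pts)          # 0.16*pi moving average with 95% CI
plot(sm)
```

A thin command-line front end over the same functions is installed at
`inst/exec/undulator` (`undulator synth | analyze | smooth | prc | simulate
| fit | gait | compare`).

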