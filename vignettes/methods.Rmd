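---
title: "Methods: GRF prediction from shank accelerometry with echo state networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GRF prediction from shank accelerometry with echo state networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`esngait` estimates the continuous z-scored vertical ground reaction
force (GRF) of one leg from a tri-axial accelerometer on the ipsilateral
shank, then reads foot-contact (FC) and foot-off (FO) events off the
predicted waveform with the same threshold algorithm used on measured
force. Two assumptions carry the whole construction:

1. **The shank acceleration determines the gait phase.** The mapping
   from recent acceleration history to the instantaneous vertical GRF is
   (approximately) deterministic within a subject and mode of
   locomotion, so a fixed dynamical system driven by the acceleration
   can represent it.
2. **A linear readout suffices.** All nonlinearity lives in the fixed
   random reservoir; only the output weights are trained, by (ridge)
   least squares, so training is convex, cheap and data-efficient —
   a handful of strides per trial.

## Preprocessing

Per trial: PCA re-orientation of the three accelerometer channels onto
the direction of maximum variance (only this first component is kept, so
the pipeline is insensitive to how the sensor was strapped on);
zero-phase 2nd-order Butterworth high-pass at 1 Hz; cumulative
trapezoidal integration to velocity and again to position; range
normalization of each trace. The three rows `(a_bar, v_bar, p_bar)` form
the network input. The GRF is decimated from 1 kHz to the accelerometer
rate 2000/14 Hz (exactly /7, anti-aliased with a Blackman windowed-sinc
FIR applied with zero phase) and z-scored per trial to give the target.

Two defaults here deviate from the narrowest reading of the published
pipeline description, for reasons the implementation forced:

* **`hp_each_stage = TRUE`.** Integrating broadband sensor noise twice
  produces an aperiodic position wander that survives a single 1 Hz
  high-pass of the acceleration. After range normalization that wander
  *is* the position row (its stride-periodic variance share is
  essentially zero), and a readout trained on scattered strides uses it
  as a per-stride timestamp: training error stays small while held-out
  R² goes negative. Re-applying the same high-pass after each
  integration restores a stride-periodic position row (periodic variance
  share ≈ 0.99) and held-out performance. The literal single-filter
  pipeline remains available (`hp_each_stage = FALSE`).
* **`pca_sign_rule = "skewness-positive"`.** A principal axis is defined
  only up to sign. Fixing the sign by the eigenvector's dominant loading
  ties it to the mounting orientation; across sensors mounted slightly
  differently the rule can flip between trials, and a tanh reservoir
  with zero initial state realizes an odd map, so one readout cannot fit
  `x` on one trial and `−x` on another. The default instead flips the
  component so its sample skewness is positive — stance loading makes
  the force-aligned component right-skewed — which is a property of the
  signal, not of the mounting, and incidentally makes `build_input`
  invariant under *any* rotation of the sensor axes.

## Reservoir and readout

The leaky echo state network uses the explicit Euler discretization
(`Δt` = 1 sample) of `dq = (1/τ)[−γq + tanh(Cq + Fx)]dt + dε`:

    q_{t+1} = (1 − γ/τ) q_t + (1/τ) tanh(C q_t + F x_{t+1}) + ε u_t

with `N = 1000` nodes, sparse `C` (density 0.05, values uniform on
(−1,1), rescaled to spectral radius 0.5), dense `F` with magnitudes
uniform on [0.1, 0.5] and random signs (`input_sign_symmetric = FALSE`
gives the literal all-positive reading of that interval — published
descriptions of this parameterization are ambiguous and both readings
are implemented), `τ = 1`, `γ = 0.5`, and uniform
state noise `ε = 1e-4` during learning only. Initial state is zero for
every segment and every continuous prediction; start-up transients are
handled by masking, below. At spectral radius 0.5 the echo-state
property is comfortably satisfied (state separation from two random
initializations contracts below 1e-6 of its initial value within 500
steps; this is one of the acceptance tests).

The readout solves `min ‖z − WQ‖² + λ‖W‖²` over the usable columns of
the concatenated training-segment states. `λ = 0` (pure pseudo-inverse
through the Gram matrix) is supported, but the **default is a weak ridge
`λ = 10`** — about 1e-3 of the state covariance scale of a typical
training set, chosen on validation splits of synthetic cohorts. With
`λ = 0` the solution exploits noise-dominated state directions: `‖W‖`
grows two orders of magnitude and the predicted swing phase jitters
around the threshold, which merges stance phases in the event detector
and inflates FO timing errors by an order of magnitude, while R² itself
also drops. Larger penalties (λ ≥ 100) oversmooth the sharp loading and
unloading flanks and degrade event timing again; the default sits in the
flat middle of that trade-off.

## Transients (the 36-sample washout)

Segments are FO-to-FO strides. Each training segment is run from
`q0 = 0` and its first 36 samples are excluded from the fit while the
reservoir entrains — a washout. The trailing 36 samples are **not**
excluded: at 2000/14 Hz a running stride is only ~103 samples and its
entire stance bump lies inside the trailing 36, so a both-sided mask
would remove every running stance sample from the training target and
make running unlearnable — which is how the implementation proved that
reading wrong. (`segment_at_foot_off()` still produces the both-sided
mask for segmented-data metrics, where symmetry is the point.)
Continuous evaluation discards the first 36 predicted samples for the
same reason; without that, the start-up overshoot corrupts the [0, 1]
scaling that the event threshold is relative to.

## Event detection

On a (measured or predicted) waveform: scale to [0, 1], smooth with an
order-1 Savitzky–Golay filter of ±30 ms (9 samples at 2000/14 Hz; in the
interior this equals a moving average), re-scale, and threshold at 12.5%
of the maximum. FC is the last sample below the threshold before an
ascending crossing; FO the first sample below it after a descending one.
Isolated single-sample spikes above *and* dips below the threshold are
ignored (the dip case would otherwise emit FO and FC at the same sample,
an invalid series). An optional `min_phase_ms` debounce is off by
default. One sample at the working rate is exactly 7 ms, which bounds
the achievable timing accuracy.

# The synthetic world

The generator produces paired accelerometer/GRF trials so the whole
pipeline is testable without recordings. Its defaults state a world
chosen once:

* 21 walking + 21 running trials by default; speeds Normal(1.24, 0.12)
  and Normal(2.20, 0.14) m/s; stride counts lognormal around 72,
  truncated to 49–116 (the reported per-trial range); stride durations
  lognormal with CV 3% around 1.10 s (walking) / 0.72 s (running),
  scaled inversely with speed.
* Walking GRF: double-bump stance (peaks at 25% and 75% of stance, peak
  1.1 body weights, valley 0.75 of peak), duty factor 0.60. Running:
  single bump peaking at 45% of stance, 2.5 body weights, an
  exponentially decaying impact spike at 8% of stance, duty factor 0.35,
  hence a flight phase. Force is exactly zero outside stance (single-belt
  convention: the instrumented belt sees one leg) and noise-free, so
  event ground truth is unambiguous.
* Stance templates carry brief (1.5% of stance) loading/unloading
  plateaus — walking 0.25/0.25 of peak, running 0/0.15 — calibrated
  once per mode so that the 12.5%-threshold crossing of the smoothed,
  resampled waveform falls within one sample of the true stance
  boundary. This is the calibration the detection loop-closure test
  demands: without a fast initial loading, a threshold crossing is
  *physically* several samples after contact and "ground truth at the
  stance boundary" would be unrecoverable by any threshold detector.
* The latent shank signal is a deterministic function of the gait
  phase: during stance a force-proportional component dominates, plus
  loading-rate, second-harmonic "tibial shock" and damped 20 Hz impact
  components; swing carries a small two-component oscillatory burst.
  The force-proportional dominance is deliberate: the reservoir at the
  stated operating point (inputs of range 1, input weights ≤ 0.5) is
  close to linear, and reported real-data results for this approach imply that the real
  accel→GRF map is largely linearly decodable. With a derivative-
  dominated latent signal no linear-readout method reaches the stated
  end-to-end targets; with large swing oscillations their leakage into
  the (constant) swing-phase force dominates the error budget. Channel
  mixing: a fixed rotation of `(s, 0.3·s phase-shifted by 5%, 0.1·s)`
  plus Gaussian noise of 5% of each channel's SD.
* Sensor mounting across a cohort: one random base orientation plus an
  independent per-trial tilt of up to 15°. Sensors strapped to shanks
  vary by small tilts, not arbitrary orientations; fully independent
  random rotations would flip the principal-axis sign on some trials
  (see above) — a failure mode of the *loading-based* sign rule the
  generator should exercise realistically, not universally.

What a green end-to-end test does establish: the full chain —
preprocessing, reservoir, ridge readout, continuation rule, continuous
prediction, threshold event detection, matching and metrics — recovers a
stride-periodic, noisy, rotated, jittered synthetic gait signal at the
stated sizes (R² ≥ 0.95, ε ≤ 10%, event MAE within 4 samples). What it
does not establish: performance on real shank accelerometry, whose
latent structure, noise spectra, artifacts and between-subject
variability the generator does not emulate; the published real-data
numbers are explicitly not reproduction targets here.

# Validation protocols

* **Segmented-train / continuous-test.** Per trial, one contiguous,
  stride-aligned window covering 50% of the strides is held out; its
  first half in time is the validation trace, the second the test trace
  (the assignment order is fixed for determinism; it is otherwise a free
  choice). The remaining strides are training candidates, subsampled
  to `round(n_strides × train_fraction)` and capped at 25 per trial.
* **Continuation rule.** Fresh reservoir seeds are drawn until every
  validation trace has positive R², up to 100 attempts; failure is a
  reported state, not an error. Seed hierarchy: master seed →
  per-repetition seed → per-attempt network seed, all derived with a
  fixed 31-bit linear map, so every run is replayable.
* **Training-size sweep.** `train_fraction` from 4% to 50% with the two
  25% holdout windows unchanged; the 25-stride cap applies throughout
  (it is a maximum, also at the smallest fractions).
* **Leave-M-out by trial.** For M = 1, one fold per trial; for M > 1, 42
  seeded distinct held-out sets (enumeration is infeasible). Held-in
  trials contribute ≤ 25 training strides and a contiguous 25%
  validation window; testing runs on the full continuous held-out
  trials.

Reported summaries are per-repetition means over trials, then mean ± SD
across repetitions.

# Numerical choices

* Butterworth design by bilinear transform with pre-warping; forward–
  backward application with odd-reflection padding and step-matched
  initial conditions (coefficients pinned against an independent
  reference implementation in the tests).
* Decimation by windowed-sinc FIR (Blackman, 20·q+1 taps, cutoff 0.95 of
  the target Nyquist), applied symmetrically: zero phase, so event times
  are not shifted by resampling.
* Integration: trapezoidal, initial value 0. z-scores use the sample SD
  (n−1). Range normalization divides by max−min without centering.
* Readout: Gram-matrix accumulation over segments; `λ > 0` by Cholesky
  solve of the regularized normal equations, `λ = 0` by eigen-based
  pseudo-inverse with a machine-precision tolerance.
* Ties and degenerate inputs: constant signals error in `scale_unit`,
  `zscore_signal`, `nrmse`, `r_squared`; event matching breaks |Δt| ties
  toward the earlier target event; a waveform that never crosses the
  threshold yields an empty series with a warning.

# Known limitations

* The stated world is far more regular than real gait; success here is
  necessary, not sufficient, for field performance.
* FO timing on predicted waveforms has a heavy-tailed error
  distribution: the unloading flank sits close to the threshold, and
  occasional prediction wiggles delay single crossings by tens of
  milliseconds. The same failure mode is known for threshold detectors applied to
  predicted waveforms in leave-M-out settings on real data.
* The CLI configuration format is JSON rather than YAML (no YAML parser
  in the dependency budget).
* `leave_m_out` with the full 21+21 cohort at N = 1000 is compute-heavy
  (42 folds × a full training each); the tests exercise it at reduced
  size.
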