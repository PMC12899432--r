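---
title: "Step detection methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Step detection methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitstep)
```

## The detection problem

A step detector maps a multi-axis inertial recording to an ordered list of
step times. The physical signal is generated by the gait cycle: each heel
strike produces an acceleration transient, each swing phase a burst of
angular rate, and the pattern repeats at the cadence (typically
0.5–3 Hz). What that pattern looks like depends strongly on where the
sensor is worn: an ankle sees sharp impact transients followed by a quiet
stance, while an arm swings like a pendulum and produces a near-sinusoid
at the step cadence. `gaitstep` implements five detectors spanning the
main methodological families — event-based thresholding (peak, adaptive),
polarity cycling (zero-crossing), frequency-domain cadence estimation
(spectral), and stance-phase/zero-velocity fusion (SHOE) — on one shared
preprocessing chain, so their differing assumptions can be compared
directly.

## Shared preprocessing

Every detector consumes the chain *magnitude → Savitzky–Golay smoothing →
median centring*:

1. **Magnitude.** The Euclidean norm of the three accelerometer axes makes
   the signal orientation independent, so no sensor-frame calibration is
   needed.
2. **Smoothing.** A Savitzky–Golay filter of polynomial order 3 removes
   high-frequency noise while preserving peak amplitude and location (the
   property threshold- and prominence-based detectors rely on). The order
   is not detector-specific knowledge; 3 is the standard choice that
   reproduces cubic trends exactly, and it is exposed as an advanced
   parameter (`sg_order`). Window lengths are specified in seconds and
   converted to samples as `round(window_s * rate)`, incremented to odd
   because the filter requires symmetric windows.
3. **Gravity compensation.** Subtracting the median isolates the dynamic
   component; the median is preferred over the mean because heel-strike
   transients are large and one-sided.

Whether smoothing precedes or follows centring is immaterial for the
result up to edge effects (the median commutes with a constant shift), so
the chain applies smoothing first, once, uniformly.

Two numerical choices matter here:

* **Edge handling.** The signal is mirror-reflected by half a window
  before filtering and trimmed afterwards, so edges see the steady-state
  kernel. The filter's native least-squares startup extrapolation can
  overshoot by more than the zero-crossing hysteresis band when gait
  activity begins within the first half window, which would fabricate a
  detection at the recording boundary.
* **Rolling statistics** (the peak detector's threshold, SHOE's stance
  statistic) use centred windows that shrink at the edges rather than
  padding, computed exactly via cumulative sums.

## The detectors and their parameters

Defaults are a single universal configuration — no scenario- or
site-specific tuning. Windows and intervals are seconds, the hysteresis
band is m/s², other thresholds dimensionless.

**Peak detection** (`peak_params()`): smoothing window 0.6 s; point-wise
height threshold = 2 s rolling standard deviation × 0.5, so the detector
self-scales from quiet standing to jogging; topographic prominence ≥ 0.2
rejects noise-floor maxima (the rolling threshold alone goes to zero on
quiet signals); minimum inter-step interval 0.35 s. The minimum distance
doubles as a physiological cadence ceiling: a spacing of *d* seconds
admits at most 60/*d* steps per minute (0.3 s → 200 steps/min). The
point-wise (rather than global scalar) threshold is a deliberate
reading of "adaptive": each candidate is compared with the local signal
energy. On conflict within the refractory interval the higher peak wins.

**Zero-crossing** (`zero_crossing_params()`): smoothing window 0.5 s;
hysteresis band 0.3 m/s²; refractory interval 0.4 s. One step is counted
per completed cycle — an excursion above +band followed by one below
−band — which suppresses chatter from oscillation about zero. The step
timestamp is placed at the linearly interpolated downward zero crossing
between the two excursions; within a cycle a later crossing supersedes an
earlier one, so the timestamp is the crossing immediately preceding the
confirming −band excursion.

**Spectral analysis** (`spectral_params()`): 8 s Hann windows with 80%
overlap; gait band 0.8–2.0 Hz. Each window's dominant frequency is the
power-spectrum argmax restricted to the band; the cadence estimate is the
median over windows; the count is `round(cadence × duration)` with
half-away-from-zero rounding; step times are placed uniformly at the
midpoints of `count` equal bins. Numerical choice: the FFT is zero-padded
(to 64× the window length, rounded up to a power of two) so the spectrum
peak is located with sub-bin resolution. The raw 800-sample window has
0.125 Hz bins at 100 Hz — coarse enough to displace a 1.1 Hz cadence to
1.125 Hz and change a 20 s count from 22 to 23; with zero-padding the
closed form `count = round(f × T)` holds exactly for pure in-band
sinusoids. Windows whose in-band power is numerically zero are skipped;
if none remains the count is zero and a warning is attached. Recordings
shorter than one window are analysed whole, flagged. This detector has no
refractory constraint — its step spacing is governed entirely by the
estimated cadence — and it is the only one whose assumptions *require*
continuous periodic gait (see the TUG failure mode below).

**Adaptive threshold** (`adaptive_params()`): all local maxima are
candidates; each candidate's amplitude is its height minus the minimum
within a centred 0.8 s window; the retention threshold is the mean
amplitude × 0.5. This two-phase scheme adapts to overall signal strength
without any absolute threshold. Thinning to the 0.4 s interval keeps the
larger amplitude, ties to the earlier peak (a fixed, deterministic
tie-break). A numerically flat signal (dynamic range below 1e−9 m/s²,
i.e. pure gravity) is short-circuited to an empty result before maxima
are sought, because at that scale "maxima" are floating-point artifacts
of the filter.

**SHOE** (`shoe_params()`): accelerometer and gyroscope magnitudes are
smoothed, min–max normalized to [0, 1], and combined as 0.7·accel +
0.3·gyro. Sliding 0.3 s windows are classified as stance when the stance
statistic falls below the threshold 9.0; one step is registered per
transition into stance (stance at the start of a recording is not a
transition), thinned to 0.35 s. The published description requires two
conditions — low acceleration variance *and* low angular rate — but a
single scalar threshold. The encoding used here is

```
stat = var_scale * var(combined) + gyro_scale * mean(gyro_n),   stance iff stat < threshold
```

with `var_scale = 1000` and `gyro_scale = 30`, both exposed as
parameters because the exact mapping is a convention of this
implementation, not recoverable from the method's description. The
defaults were chosen so that each term alone can veto stance: a window
with normalized-combined variance above ~0.009, or a mean normalized
gyro above 0.3, is rejected. A smaller gyro scale (e.g. 10) lets windows
in mid-swing — quiet accelerometer, gyro around half scale — classify as
stance and double-count strides. The step is registered at stance
*onset*; midpoint or offset registration would be equally defensible, and
onset was fixed for determinism. Two degraded paths carry warnings:
without a gyroscope the combined signal is the normalized acceleration
alone, and when no stance window exists anywhere (common off the foot)
the detector falls back to peak detection on the combined signal.
Min–max normalization makes the detector invariant to positive rescaling
of each channel — the threshold needs no units.

## Evaluation

`match_steps()` computes a maximum-cardinality one-to-one matching
between detections and references under `|d − r| ≤ tolerance` by greedy
leftmost pairing over the sorted sequences. On a line with a uniform
window the greedy matching is optimal (any crossing pair can be
exchanged); the test suite nevertheless checks it against an exhaustive
dynamic program on 1000 random instances. The default ±0.3 s tolerance
reflects the timing uncertainty of manual annotation (about 1.5× a
typical reaction time). Degenerate metric cases use the 0/0 → 0
convention so that batch runs score empty outputs rather than crash.

Percentiles in `plausibility_screen()` use the nearest-rank method so
summaries of integer step counts are themselves integers, and the
plausible range (default 4–20 steps) is inclusive at both ends. The
screen is a coarse instrument by design: it flags gross failures (zero or
hundreds of detections on a ~13 s TUG trial), not clinical norms.
`bilateral_consistency()` reports the mean and sample standard deviation
(n−1; a single pair yields SD 0 with a warning) of absolute left/right
count differences. Per-trial F1 values are averaged when aggregating, not
recomputed from pooled counts; pooled counts remain available from the
returned objects for users who prefer the other convention.

## The simulator

`simulate_recording()` exists so that every detector and metric can be
exercised with exact, continuous ground truth. It emulates the features
of real walking data that the detectors key on:

* **Step timing.** Steps sit at the midpoints of a cadence grid
  (`(k + 0.5)/cadence`), perturbed by Gaussian jitter with SD 2% of the
  period, clamped at ±2 SD so consecutive steps always remain at least
  0.8 periods apart. With duration × cadence not half-integer this makes
  the ground-truth count exactly `round(cadence × duration)`.
* **Mounting morphology.** Ankle: a sharp biexponential impact at each
  step, preceded by a biphasic (negative-then-positive) swing
  oscillation built from raised-cosine lobes, followed by quiet stance;
  the gyroscope carries a plateau burst across the swing and is silent in
  stance. Upper arm: a sinusoid at the cadence. Wrist: the arm sinusoid
  plus seeded, sporadic low-amplitude gesture artifacts. Thigh: an
  attenuated impact plus a sinusoid. Raised-cosine lobes were chosen over
  half-sines deliberately: their zero end-slope keeps the smoothing
  filter from ringing at lobe boundaries, which would otherwise seed
  spurious low-amplitude maxima.
* **Phase convention.** The oscillatory component peaks one eighth of a
  period *before* the annotated step time. This places the waveform
  maximum (what peak/adaptive detect) at −T/8 and the following downward
  zero crossing (what the zero-crossing detector timestamps) at +T/8 —
  symmetrically inside the ±0.3 s matching window even at the slowest
  supported cadence. With the maximum at the step itself, the zero
  crossing would drift to +T/4 ≈ 0.28 s at 0.9 Hz and jitter would push
  it over the tolerance.
* **Scenarios.** Stair descent multiplies amplitudes by 1.25 and ascent
  by 0.85 (gravitational assistance raises descent impacts); jogging uses
  1.8× amplitude at 2.5 Hz default cadence; the TUG scenario emits sit →
  stand-up transient → walk bout → turning burst → walk bout → sit-down
  transient, with ground-truth steps only inside the bouts and defaults
  (5 steps per bout, ~13 s total) inside both the 4–20 plausible-count
  band and the 10–15 s trial-duration convention; `stationary` is gravity
  plus noise with empty truth.
* **Noise.** Additive Gaussian, default SD 0.15 m/s² per accelerometer
  axis (a realistic consumer-IMU noise floor including soft-tissue
  artifact), gyroscope noise 5× that in deg/s. All randomness flows from
  the spec's single seed; identical specs give bit-identical output and
  the caller's RNG stream is left untouched.

Every shape parameter lives in one config block
(`morphology_defaults()`) so fixtures remain tunable without touching
code.

**What passing tests do and do not show.** The simulator produces
idealized single-subject signals: stationary cadence within a scenario,
stereotyped waveforms, no sensor drift, saturation, soft-tissue wobble,
uneven terrain, or pathological gait (shuffling, hemiparesis, assistive
devices). Perfect recovery on noiseless simulated walking therefore
demonstrates that the implementations are faithful and self-consistent —
not that any detector achieves a particular accuracy on real recordings.
Conversely, the simulated failure modes (spectral overestimation on TUG,
SHOE's dependence on true stance phases) are structural properties of the
algorithms and do transfer.

## File formats

The canonical CSV schema is one header row —
`time_s, s1_ax..s1_mz, s2_ax..s2_mz, step_marker` — with timestamps in
seconds from recording start, accelerometer in m/s², gyroscope in deg/s,
and ground truth as a 0/1 marker column (a single self-contained file per
trial). The writer is deterministic (fixed column order, 10 significant
digits — nine plus a guard digit so numeric round trips stay within 1e−9
relative error); marker storage quantizes step times to the sample grid,
at most half a sample period (5 ms at 100 Hz), an order of magnitude
below the matching tolerance. Foreign dialects are ingested through
`column_mapping()`, which renames columns, converts g → m/s² (×9.80665)
and rad/s → deg/s, and normalizes second/millisecond/sample-index
timestamps; no dialect presets ship, only the mechanism.
`resample_recording()` interpolates linearly onto a uniform grid —
adequate for rate harmonization of gait-band signals, not an
anti-aliased decimator.

## Problem sizes

The test and acceptance workloads use 100 Hz recordings of 20–60 s:
long enough for at least eight spectral windows and 27–90 steps, small
enough that the full suite (≈1900 assertions, including 16 simulated
parameter-recovery runs and the 1000-instance matcher oracle) completes
in well under a minute. These sizes are the package's own validation
choices; all functions operate on arbitrarily long recordings.

## Known limitations

* The SHOE stance statistic is one defensible encoding of a two-condition
  rule behind a single threshold; with other data sources its scale
  factors may need re-tuning, which is why they are parameters.
* Spectral step *times* (uniform placement) are a convention; only the
  count is meaningful when cadence varies.
* The batch tool pairs bilateral sensors by `left`/`right` tokens in file
  names, because the canonical CSV carries no metadata header.
* Detectors process complete recordings; no streaming state is kept
  between calls.
* Magnetometer channels are carried through I/O but unused, and no
  orientation estimation or activity segmentation is performed —
  recordings containing long non-walking stretches should be segmented
  upstream for the detectors whose assumptions require it.
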