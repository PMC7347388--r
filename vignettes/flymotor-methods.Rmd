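---
title: "Measuring motor neuron recruitment in the fly leg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring motor neuron recruitment in the fly leg: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymotor)
```

`flymotor` measures how a pool of motor neurons divides the work of
flexing the *Drosophila* femur–tibia joint: a tonically active *slow*
unit maintaining posture with tiny force increments, *intermediate*
units covering the mid-range, and a phasic *fast* unit for ballistic
movements. This vignette documents the models behind each analysis
stage, the tunable parameters, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The force probe as a damped harmonic oscillator

The fly pulls on a flexible fiber whose deflection reports force. At
steady state the probe is a linear spring, `F = k x`; transiently it
also carries effective mass and drag:

$$ F(t) = m\,\ddot x + c\,\dot x + k\,x. $$

We work in units in which the equation is self-consistent without
conversion factors: displacement in µm, time in ms, force in µN, mass
in mg and drag in mg/ms (1 mg·µm/ms² = 1 µN). The defaults of
`probe_model()` are the calibrated constants k = 0.2234 µN/µm,
m = 0.1702 mg and c = 0.1377 mg/ms. Drag in mg/ms is the reading under
which the derived ring-down constants are dimensionally consistent:
τ = 2m/c ≈ 2.47 ms and damped period 2π/ω_d ≈ 5.86 ms, i.e. the probe
settles within a single 170 Hz video frame. (Quoting the same drag in
kg/s — a factor 10³ larger — would put the probe deep into overdamping
and contradict the observed oscillatory ring-down.)

* `simulate_probe_response()` integrates the equation of motion with a
  fixed-step fourth-order Runge–Kutta scheme at a 0.05 ms substep.
  τ ≈ 2.5 ms demands sub-millisecond resolution; the input force grid
  must satisfy `dt ≤ 0.1 τ`, and coarser output rates are obtained by
  decimating afterwards. Against the closed-form underdamped solution
  the integrator is accurate to ~10⁻⁷ relative error.
* `fit_flick_dynamics()` extracts m and c from a "flick": the probe is
  deflected and released, and the free response
  `A e^{-t/τ} cos(ω_d t + φ) + b` is fitted by Levenberg–Marquardt
  nonlinear least squares (the fitting procedure is our choice; only
  the model form is dictated by the physics). Starting values come
  from the log-envelope of the rectified extrema (τ) and the dominant
  FFT component (ω_d) — the spectral start is what makes the fit
  robust to tracking noise. If the centred trace never crosses zero
  after release (ignoring fluctuations below 5% of the peak) the
  response is declared overdamped and a biexponential is fitted
  instead, with m = k/(r₁r₂) and c = m(r₁ + r₂).
* `reconstruct_force()` defaults to the quasistatic reading `F = k x`,
  which is accurate to ~2% for movements band-limited below ~5 Hz and
  is the right choice at the 170 Hz video rate. Dynamic mode adds the
  drag and inertia terms using fourth-order central-difference
  derivatives of a Savitzky–Golay smoothed copy of the trace (window
  7, order 2 — the smoothing suppresses tracking jitter, and the
  spring term always uses the raw positions so smoothing cannot bias
  the dominant term). Second-order differences at 170 Hz would lose
  ~15% of the velocity term above 25 Hz; the fourth-order stencils
  keep the full reconstruction within 2% RMS for forces band-limited
  below 50 Hz.
* `displacement_to_joint_angle()` converts probe displacement to joint
  rotation as `asin(d / lever arm)` with a 417 µm default lever arm.
  Over the ±150 µm working range, arcsine, arctangent and the
  small-angle approximation agree within half a degree; arcsine is the
  chord-on-radius reading of the geometry and reproduces the printed
  conversions (60 µm ≈ 8°, 75 µm ≈ 10°, 150 µm ≈ 21°).
* `track_probe_position()` finds the probe in a video frame by
  resampling the image along a user-drawn axis (bilinear
  interpolation), averaging across the probe width, and taking the
  centre of mass of the intensity profile within ±FWHM of its peak
  above baseline. The baseline is the profile median — robust to
  bright clutter — and a frame with no peak at least 3 noise s.d.
  above baseline is flagged invalid rather than producing a spurious
  position.

## Muscle activity clusters from calcium movies

Motor units are mapped by grouping pixels whose GCaMP fluorescence
co-varies. `cluster_pixels()` z-scores each pixel's time series and
runs standard k-means with multiple restarts; on standardised series,
squared Euclidean distance is exactly 2(1 − r) for Pearson correlation
r, so this is correlation-metric k-means computed by `stats::kmeans`.
Zero-variance pixels are excluded up front, and labels are renumbered
ventral to dorsal so cluster numbers are comparable across sessions.
The default k = 6 matches the femur field of view; planted-partition
tests use the known k.

`refine_cluster_map()` applies the neighbourhood-support rule: each
cluster's indicator image is smoothed with a Gaussian kernel
(σ = 2 px by default; the support threshold 0.75 is the operative
parameter) and pixels whose smoothed same-label support falls below
0.75 are dropped. The smoother is a small separable convolution with
zero padding and a unit-sum kernel, written in the package because the
boundary semantics are part of the rule: a solid region must smooth to
exactly 1 in its interior so that only rims and strays are removed.

`extract_cluster_traces()` averages member pixels per frame and
normalises to ΔF/F with F0 equal to the 10th percentile of the
cluster's trace — a baseline that stays meaningful even when the
muscle is active much of the time. When the force probe (or any
occluder) covers more than 40% of a cluster's pixels in a frame, that
frame is invalidated for that cluster; below the threshold, the mean is
taken over the visible pixels only.

`detect_activations()` exploits the separation of timescales: the
indicator decays over hundreds of milliseconds while leg movements are
much faster, so a *negative* derivative of cluster fluorescence can
only be noise. The trace is Savitzky–Golay filtered (polynomial order
7, frame length 9 — both configurable, since the order/length
convention differs between implementations) with the derivative taken
from the same local fit, interpolated onto the video-rate grid, and
the noise s.d. is estimated from the negative derivative samples
mirrored about zero. Activations are contiguous runs of derivative
above twice that s.d. Raising the multiplier can only shrink the
activated set (a property the tests assert). Note the 2 s.d. threshold
implies a few isolated false-positive samples per minute on quiet
clusters; analyses that need hard guarantees should filter activations
by duration.

## Template spike detection with dynamic time warping

Spikes are detected in four steps. (1) The first difference of the
trace (scaled by the sampling rate) is passed through causal 3-pole
Butterworth filters, high-pass 209 Hz then low-pass 898 Hz; the rapid
reversal of membrane potential at the spike peak produces a large
positive deflection in this band. Filters are causal rather than
zero-phase so that onset latencies and conduction delays remain
meaningful. (2) Candidates are local maxima above a threshold with at
least 1 ms separation (fly spikes are ~2 ms wide); the default
threshold is 5 robust s.d. of the filtered trace. (3) Each candidate's
251-sample window is compared to a per-cell template by dynamic time
warping — full alignment, squared local cost, no band constraint —
which tolerates the small timing jitter that would dominate a plain
Euclidean distance. The DTW recursion is implemented in C++ and is
tested for exact agreement against a brute-force full-matrix dynamic
program. (4) Candidates are accepted when the DTW distance is at or
below the shape cutoff *and* the raw-trace amplitude (local peak minus
the preceding baseline median) is at or above the amplitude cutoff.

The original workflow set the two cutoffs interactively per cell; here
explicit values always override, and the automatic default clusters
candidates in (log distance, amplitude) with 2-means and accepts the
high-amplitude/low-distance component only if the two components are
clearly separated (difference of mean amplitudes exceeding twice the
summed within-component s.d.). The separation guard is what makes the
auto mode specific: on a pure-noise trace the two components are
indistinguishable and nothing is accepted. Templates
(`estimate_template()`) are the mean of peak-aligned windows with one
refinement pass dropping events beyond the 90th percentile of DTW
distance to the provisional mean; when no seeds are given the top 20
candidates by peak height are used. EMG events of inverted polarity
are handled by setting `invert = TRUE`. Spike onsets
(`locate_onset()`) are the maximum of the second difference of the raw
trace, smoothed over 5 samples, within the half window preceding the
peak — the point of maximal acceleration of the membrane potential.

On synthetic 50 kHz traces with spikes at 10:1 amplitude-to-noise, the
detector reaches recall and precision of 1.0 at ±1 ms tolerance with
fully automatic cutoffs.

## Joint angles from tracked points

The tibia sweeps a circular arc in a plane tilted out of the camera
plane by the azimuthal angle (~50–65° in the rig), so the tracked
tibia centroid traces an ellipse whose minor/major axis ratio is
cos(azimuth). `clean_points()` first repairs tracking failures: per
frame, each tibia point's nearest-neighbour distance is compared to
the pooled distribution (robust z-score from median and MAD, cutoff 5);
exactly one outlying point is re-drawn — placed to minimise the squared
deviation from partner distances sampled from the per-pair empirical
distributions, a concrete instantiation of "fill from the pairwise
distance distribution" — while two or more outliers exclude the frame.
Coordinates are then median-filtered over 5 frames and the tibia
centroid appended.

`fit_arc()` fits the centroid ellipse by the direct least-squares
conic method (the ellipse-constrained generalized eigenproblem),
implemented here because no installed package provides it; it is
closed-form, rotation/translation invariant, and its azimuth estimate
is invariant to isotropic scaling. `joint_angles()` unprojects each
centroid (the minor-axis coordinate is multiplied by a/b) and measures
the joint angle as the angle at the arc centre between the unprojected
femur direction and the unprojected centroid direction, so 180° is a
straight leg; frames whose radial residual exceeds 3 robust s.d. are
flagged. Postures are labelled extended above 120° and flexed below
30°. The full round trip — generate points at 1 px tracking noise,
clean, fit, unproject — recovers the commanded angle series with RMS
error below 1° and the azimuth within 1° across 50–65°, provided the
sweep is sampled densely (≥ ~150 frames per waving cycle, as a 170 Hz
camera provides; much sparser sampling lets the median filter clip the
sweep extremes and bias the fitted ellipse).

## Recruitment statistics

`spike_triggered_hist()` gathers all video frames in the 25 ms after
each spike and forms the 2-D histogram of probe force and velocity.
The centroid is the mass-weighted mean of the contributing frame
values, computed before any log display scaling. Frames shared by
overlapping windows are counted once per contributing window by
default; both conventions are available (`dedupe`) because the choice
is not dictated by the definition. Velocity comes from
`probe_velocity()`: central differences of the Savitzky–Golay smoothed
positions (window 5, order 2) at the video rate. Stationary "hotspots"
(the probe parked at zero or at full pull) can be masked via
`exclude_bins`.

`force_per_spike_curve()` averages aligned, baseline-subtracted probe
traces within each spike count, takes each average's peak, fits a
free-intercept line (slope = gain in µN/spike) and reports the
two-spike/one-spike peak ratio. `preceding_firing_rate()` counts
reference-train spikes in the 30 ms before each event.
`rise_metrics()` reports the time to half-maximum (linear
interpolation between frames) and the rising-phase slope fitted
between 10% and 90% of peak.

## Behavioral endpoints and resampling statistics

`percent_speed_change()` is 100 × (mean speed from just after stimulus
onset through stimulus + 200 ms, minus the speed at onset) / speed at
onset; trials with zero onset speed are undefined and flagged NA.
`walk_initiation()` requires sustained walking above 3 mm/s in the
500 ms after onset, with "sustained" quantified as at least 50% of the
window above threshold (configurable — the qualitative word needs an
operational definition).

`bootstrap_two_sample()` pools both groups, draws group-sized samples
with replacement (so draws are proportional to each group's trial
count), and takes the two-tailed p-value as the fraction of draws
whose absolute difference in the statistic meets or exceeds the
observed one. "More extreme, two-tailed" is operationalised as the
absolute difference, and add-one smoothing ((count + 1)/(draws + 1))
prevents p = 0 at finite draws. Trials are resampled flat; the
per-fly nesting of real experiments is not represented in the trial
table, so a block bootstrap is out of scope here. `bh_fdr()` is the
standard Benjamini–Hochberg step-up, with adjusted values from
`stats::p.adjust`; the tests verify the rejection set against a
literal implementation of the step-up definition.

The type-I calibration checks run 1,000 replicate null experiments at
2,000 draws each; the rejection rate at α = 0.05 is insensitive to the
draw count well below the study's 10,000 draws, which remain the
default for actual comparisons.

## What the synthetic data emulate — and what they do not

The generators define the reference conditions under which the
pipeline is validated; their defaults are fixed once and are not
tuned per test.

* `simulate_session()` drives three neuron types from a common
  smoothed random-telegraph drive (levels 0/0.55/0.95, mean dwell 2 s,
  100 ms smoothing; the first three segments visit all three levels so
  every regime occurs even in short sessions). The slow neuron fires
  as an inhomogeneous Poisson process around 30 Hz at rest (intensity
  compensated for a 2 ms refractory period so the realised rate
  matches), modulating with drive; intermediate and fast units
  recruit above drive thresholds of 0.45 and 0.75. Resting potentials
  are −48/−60/−68 mV and per-spike forces 0.08/1/10 µN for
  slow/intermediate/fast. Within every high-drive epoch the ground
  truth enforces slow-before-intermediate-before-fast first-spike
  order by deleting violating spikes — the recruitment hierarchy is
  true by construction, which is exactly what makes it a useful
  benchmark for the spike-triggered statistics. Spikes are ~2 ms
  biexponential waveforms (rise 0.2 ms, decay 0.6 ms; amplitudes
  4/8/12 mV) inserted one-per-ground-truth-spike into Gaussian-noise
  voltage traces at 50 kHz; the EMG carries only intermediate and
  fast units, the small slow axon being invisible extracellularly.
  Twitches are difference-of-exponentials kernels (rise/decay 20/200 ms
  for slow — the slow fibre's kinetics are not quantified in the
  source experiments, so this is a configurable package choice — and
  3/40 ms for the others), summed with facilitation and fed through
  the probe model at a 0.2 ms grid before decimation to 170 Hz.
* Facilitation: the n-th spike of a burst contributes
  `facilitation^(n-1)` of the first spike's force increment; at the
  default 0.6 two near-coincident spikes peak at ~1.6× one spike and
  the increments saturate by ~10 spikes. `simulate_twitch_trials()`
  spaces intra-burst spikes 1 ms apart by default so that peak forces
  superpose almost exactly; with linear summation
  (`facilitation = 1`) the fitted gain then equals the per-spike force
  within 2% by construction, which pins down the estimator rather
  than the muscle model.
* `simulate_muscle_movie()` convolves per-cluster activation trains
  with a GCaMP-like difference-of-exponentials kernel (rise 50 ms,
  decay 300 ms — "slow relative to leg movements" made concrete) and
  adds i.i.d. pixel noise; an optional occluder zeroes pixels and its
  per-cluster coverage is logged exactly. `simulate_leg_points()`
  implements the projected-arc geometry with Gaussian jitter and
  rare single-point tracking failures (default magnitude 50 px).
  `simulate_behavior_trials()` produces Bernoulli walk-initiation
  outcomes and walking-speed traces with a stimulus-locked
  multiplicative speed change.

All generators take a seed and return identical output for identical
seeds. What they deliberately do **not** emulate: photobleaching,
motion artefacts and non-rigid deformation in movies (frames are
assumed registered); correlated or 1/f noise in electrophysiology;
electrode drift and current-injection artefacts; pose-estimation
failure modes other than isolated point misplacements; per-fly random
effects in behaviour. Passing the synthetic benchmarks therefore
demonstrates the correctness of the algorithms under the stated noise
models, not robustness to every artefact of real recordings.

## Problem sizes and runtime choices

The validation suite sizes its simulations to run in minutes on one
CPU: 60 s single-unit traces for detector recall/precision, 20
sessions of the default 60 s duration for the recruitment-ordering
sign tests, 600-frame sweeps for the kinematic round trips, 100 seeds
for calibration recovery, and 1,000 replicate experiments for
bootstrap calibration. These sizes give the directional tests
overwhelming power (a sign test over 20 seeds resolves p < 10⁻⁵ when
all seeds agree) while staying lightweight.

## Known limitations

* Quasistatic force readings underestimate true force whenever the
  probe moves out of the imaging plane; no out-of-plane estimation is
  attempted.
* The correlation k-means segmentation assumes registered frames and
  stable cluster geometry over the session.
* The automatic cutoff clustering in `detect_spikes()` assumes a
  single spike-generating unit per trace; multi-unit EMG sorting
  beyond one template is out of scope.
* The joint-angle unprojection treats the femur direction as lying in
  the plane of the arc; a femur tilted relative to the swing plane
  would add a fixed angular offset.
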