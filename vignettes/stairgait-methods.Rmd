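---
title: "Methods: stair-aware gait analysis from foot-worn IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stair-aware gait analysis from foot-worn IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`stairgait` turns continuous two-foot IMU recordings (3-axis accelerometer
in g, 3-axis gyroscope in dps, 204.8 Hz) into per-activity digital mobility
outcomes, keeping stair ascent and descent as first-class gait activities.
This vignette describes each model in the chain, the parameters that matter,
the synthetic generator used for validation, and the design decisions made
where the problem left genuine freedom.

## Coordinate transformation

Sensors are mounted on the shoe instep with only rough physical alignment,
so each recording is rotated into a body frame using gravity. Static
periods are windows of at least 1 s in which the Euclidean norm of the
angular rate stays below 2.5 dps; the norm is used because it is invariant
to the (unknown) sensor orientation. The mean static acceleration ā_s is
rotated onto e_g = (0, 0, 1) by the axis–angle rotation with axis
ā_s × e_g and angle arccos(ā_s·e_g/‖ā_s‖). Two degenerate cases are fixed
deterministically: if ā_s is already parallel to e_g the rotation is the
identity; if it is anti-parallel the axis is taken as (1, 0, 0) with angle
π (any axis orthogonal to gravity is equally valid; one is chosen for
reproducibility). After alignment the axes are relabelled ml
(medial–lateral), pa (posterior–anterior), si (superior–inferior); during
quiet standing acc_si ≈ +1 g and acc_ml ≈ acc_pa ≈ 0 g.

Left-foot data additionally have the ml axis negated so foot flexion has
the same sign on both feet and the terminal-contact dip is negative
everywhere. The negation is a signal-level convention: for sagittal-plane
gait (gyr_pa ≈ gyr_si ≈ 0, acc_ml ≈ 0) it coincides with the full mirror
reflection up to terms that vanish identically.

Gravity alignment can only observe tilt, not rotation about gravity
itself, so mounting rotations are assumed to have no twist component about
the vertical; this is what instep-clip mounting provides in practice.
Static windows are pooled per recording by default (configurable).

## Multiclass HMM stride segmentation

Features are computed at 51.2 Hz: the body-frame gyr_ml and acc_si are
decimated by 4, low-pass filtered (4th-order Butterworth, 10 Hz,
zero-phase), and complemented by a sliding centred-window linear gradient
(200 ms window, ≈ 11 samples; the gradient is the slope of the
least-squares line, with symmetrically shrunken windows at the edges).
The four columns are z-score standardized per walking bout — at prediction
time with the bout's own statistics, which keeps the model free of any
global scaler.

Four Gaussian-mixture HMM sub-models share this feature space:

| sub-model   | states | topology |
|-------------|--------|----------|
| transition  | 5      | chain with self-loops plus dense first row and first column, last-state self-loop |
| level       | 20     | left–right (self + next state only) |
| ascending   | 20     | left–right |
| descending  | 20     | left–right |

Each state emits from an 8-component diagonal-covariance Gaussian mixture.
Sub-models are trained with 10 iterations of Baum–Welch, **one training
sequence per stride** (border to border): the left–right chain models the
phase progression of a single stride, and repetition is expressed by the
combined model's self-restart edges. Training on multi-stride runs instead
lets one chain pass absorb several strides and destroys border recall —
this is the single most consequential implementation choice in the module.

Initialization: the left–right transition matrix starts dwell-matched
(self-probability 1 − K/T̄ for mean stride length T̄ frames); emissions are
initialized by splitting every training sequence into K equal-length
segments, pooling segment k across sequences, and running k-means with 8
centres (fixed seed, variances floored at 10⁻³ on the z-scored scale).
Structural zeros of the topology and of the initial distribution are
preserved exactly by EM; the training log-likelihood is asserted
non-decreasing.

The combined 65-state model is block-diagonal in the four sub-models plus
explicit border edges: from **every** transition state to each stride
model's first state, from each stride model's last state to **every**
transition state, self-restarts (last → first within a stride model), and
level↔stair switches (level-end → ascending/descending-start and
vice versa). Direct ascending↔descending switches are not allowed. Each
inserted edge receives the mean outgoing probability of its source row
before the row is renormalized. The initial state distribution is uniform
over transition states and the three stride start states.

Prediction uses log-space Viterbi (ties toward the lower state index).
Any border-edge transition in the decoded path is a stride border; borders
are mapped back to the original rate (×4) and snapped to the raw gyr_ml
minimum within ± 150 ms. Candidate strides then pass the annotation-rule
filter: gyr_ml at the start border ≤ −20 dps, in-stride swing maximum
≥ +50 dps, duration within 0.4–2.5 s. Sub-model labels are retained for
diagnostics but deliberately not used for final stride typing — typing is
done from spatial trajectory features, which proved far more reliable than
HMM state labels.

Recordings at rates other than 204.8 Hz are linearly resampled first,
since every window length in the pipeline is defined in milliseconds
against that rate.

## Gait-event detection

A strict per-stride event order is assumed: TC < swing-max < facc-max <
IC < MS < next TC. The evaluation order is TC refinement → swing maximum →
MS → forward-acceleration maximum → IC, because the facc/IC search windows
need MS:

- **TC**: minimum of the zero-phase 10 Hz (order 5) filtered gyr_ml within
  ± 150 ms of the segmentation border (window clipped at edges).
- **Swing maximum**: first peak of the 5 Hz (order 5) filtered gyr_ml
  strictly between consecutive TCs with prominence ≥ 20 dps ("first
  prominent peak"; the prominence floor is our reading of *prominent*).
- **MS**: centre of the 200 ms window with minimum total 3-D angular-rate
  energy between the raw gyr_ml maximum and the next TC; ties resolve to
  the earliest centre; intervals shorter than the window fall back to the
  interval centre and are flagged.
- **Forward-acceleration maximum**: maximum of the 5 Hz filtered acc_pa
  between the swing maximum and MS.
- **IC**: within the first 60 % of the facc-max→MS window, the maximum of
  acc_pa² if it reaches 4 g²; otherwise the maximum central first
  difference of the filtered acc_pa (fallback for strides without an
  impact peak, common on stairs).

Temporal parameters use the event times directly, so
swing + stance = stride holds exactly in sample arithmetic. Strides are
flagged invalid outside swing ∈ [0.2, 1.0] s, stance ∈ [0.2, 1.5] s,
swing ratio ∈ [25 %, 60 %] (the published swing bound is read as an
interval, consistent with its companions). Event-order violations
invalidate the stride rather than aborting the bout.

## ZUPT-aided trajectory reconstruction

Zero-velocity samples are the OR of three boolean detectors: (i)
acceleration magnitude — the deviation of ‖acc‖ from 1 g stays below
0.1 g throughout the sample's centred 150 ms window; (ii) gyroscope
energy — the RMS of ‖gyr‖ over the centred 150 ms window is below 10 dps;
(iii) an enforced 50 ms window centred on each MS event, which guarantees
at least one ZUPT period per stride even in fast stair walking. The
centred per-sample statistic (rather than marking every sample of any
qualifying window) is deliberate: window-marking labels late-swing samples
stationary whenever a window straddles swing and stance, which injects
false zero-velocity measurements at ≈ 1 m/s foot speed.

Walking sequences are split at orientation-update windows: maximal runs of
at least 300 ms in which each accelerometer axis variance stays below
0.015 g², with updates forced at the sequence start and end (best-effort
local statistics and a warning if those are not static). The window centre
provides a gravity-referenced orientation from low-pass-filtered
acceleration — roll/pitch only; yaw is unobservable and set to zero per
subsequence, which is sufficient because stride length uses the horizontal
norm and stride height the vertical axis, both yaw-invariant.

Within each subsequence the nominal state (position, velocity, quaternion
orientation) is propagated by strapdown integration (midpoint gyro rule,
trapezoidal velocity/position). A 9-dimensional error state (δp, δv, δθ)
is tracked open-loop: δp′ = δv, δv′ = −[R f]× δθ, δθ′ = 0 plus noise, with
zero-velocity measurements z = −v_nominal on ZUPT samples. The error state
and covariance are smoothed backwards (Rauch–Tung–Striebel) and applied
once, which avoids the position discontinuities a closed-loop update would
create. Subsequences are stitched with positional continuity. No
level-ground (zero-z) assumption is made anywhere — it would be violated
on stairs — and no heading correction is applied.

Noise defaults (config-exposed): gyro 0.02 dps/√Hz, accelerometer
0.002 g/√Hz, ZUPT measurement SD 0.01 m/s. The error-state formulation is
insensitive to these within an order of magnitude on clean data; they are
starting points for real recordings, where only known stair-step heights
are usually available for tuning. Units are converted to SI (9.81 m/s²
per g) only inside this module; the world frame has z up, so stride
height is positive for ascent.

Spatial features per stride i use the trajectory at consecutive MS events:
S_d = Trajectory_d(MS_i) − Trajectory_d(MS_{i−1}), height = S_z,
length = √(S_x² + S_y²), inclination = arctan(height/length). A zero-length
stride with non-zero height reports ± 90° and is flagged.

## Classification, bouts, DMOs

A stride is **ascending** only if height ≥ +0.10 m *and* inclination ≥ +6°,
**descending** only if height ≤ −0.10 m and inclination ≤ −6° (inclusive
thresholds; chosen against the flattest staircase geometry, 13 cm / 7.6°,
so single-step strides still qualify). Everything else is level. Strides
with length < 0.25 m or > 2.0 m, or failing the temporal bounds, are
rejected before bout assembly. By construction ascending and descending
are disjoint.

Bouts are runs of alternating-feet strides with inter-stride gaps ≤ 2.5 s.
Stair bouts need at least 5 consecutive same-type stair strides; by
default brief level interruptions within the gap bound do not split a
stair run (configurable, `merge_interrupted`), reconciling the
interruption example with the minimum-count rule. Stair runs below the
minimum are re-labelled level walking, which trades stair recall for high
stair precision — the intended operating point. Level bouts require at
least two strides per foot. DMOs are per-activity means and standard
deviations of stride, swing and stance times; the SD divisor is n
(population convention, configurable) so a single stride reports SD 0.

## Pressure-insole reference

The conditioning circuit follows V_out = V_ref (1 + R_ref/R_FSR) with
V_ref = 0.1 V; channel loads are summed per sample and per-stride minimum
baselines subtracted (global minimum when no borders exist, e.g. at
prediction time). Reference IC/TC are the upward/downward crossings of
7.5 % of body weight, localized at the first sample beyond the threshold
(no sub-sample interpolation; the reference should share the IMU's
resolution).

## Segmentation and event evaluation

A predicted stride is a true positive when **both** borders lie within
± 100 ms of a reference stride's borders, each reference matched at most
once (greedy in time order; verified against exhaustive optimal assignment
on small instances). Precision, recall and F1 follow the usual formulas
with zero-denominator cases reported as 0. Event-timing errors are signed
(predicted − reference) in ms with mean, SD and MAE.

## The synthetic generator

The study data behind this pipeline are not publicly available, so
validation uses a generator that emulates the relevant signal physics.
Per-stride kinematics are composed of raised-cosine velocity and
angular-rate primitives with closed-form position, velocity and
acceleration; the emitted accelerometer signal is exactly the second
derivative of the ground-truth trajectory projected through the
ground-truth orientation plus gravity, and the gyroscope is exactly the
body-frame angular rate of that orientation. Consequently, integrating the
emitted noise-free signals recovers the ground-truth trajectory (within
1 mm over a stride when the quadrature respects the smooth underlying
signal, e.g. via cubic-spline reconstruction — plain trapezoid sums are
limited by their own truncation error at ±7 g foot accelerations and
204.8 Hz sampling).

Morphology per stride (fractions of the swing duration, 42 % of the
stride): a terminal-contact dip (−160 dps or 0.7× the swing peak if
larger) centred on the border, a swing peak (+200/+150/+250 dps for
level/ascending/descending), and a second dip around initial contact
sized so the net rotation per stride is zero. Forward motion is a main
velocity bump plus a late surge with a gentle rise and a sharp brake —
the braking peak is the squared-acc IC marker (≥ 2 g at all speeds).
Vertical motion combines the net rise required by the stride spec
(0 for level; ±2 × rise for double-step stair strides) with a 5 cm
clearance bump. Stair geometries follow the three staircase
configurations (rise/run 17.5/26.5, 14.5/35, 13/97 cm); speeds scale the
base durations (1.10/1.25/1.15 s) by 1.25 / 1.00 / 0.80. Insole channels
emit raised-cosine stance pulses (20 ms edges) whose contact intervals
coincide exactly with the ground-truth IC–TC intervals, plus a 0.5 kg
lacing baseline.

Ground-truth events are analytic (bump centres), with two deliberate
exceptions: MS truth is the centre of the earliest fully quiet 200 ms
window (stance angular rate is exactly zero, so the minimum-energy window
ties and the earliest-index tie-break defines the event), and
forward-acceleration-maximum truth is computed from the generator's own
noise-free clean forward acceleration, because that event is defined on
the 5 Hz filtered signal and has no filter-free location.

**What passing these tests shows — and what it does not.** The generator
provides stereotyped, perfectly repeatable strides with white Gaussian
noise (defaults 0.01 g, 0.5 dps — conservative, so test tolerances probe
the pipeline rather than the generator), tilt-only mounting error, no
gyroscope bias drift, no soft-tissue artefacts, no turning, shuffling or
non-gait cyclic movement, and no pathological gait. Perfect synthetic
scores therefore demonstrate correctness of the algorithms under their
stated assumptions, not expected performance on real patient data.

## Numerical choices and degenerate inputs

- Zero-phase filtering pads by odd reflection with a pad that outlasts the
  filter's settling time (3 · order · fs/cutoff samples).
- Viterbi runs in log space; all argmin/argmax ties resolve to the
  earliest index; k-means initialization is seeded.
- Mixture variances are floored at 10⁻³ (z-scored features); mixture
  weights at 10⁻⁸.
- Constant feature columns raise an error naming the column (a bout with
  no signal variation cannot be standardized).
- Intervals are half-open, 0-based sample indices everywhere.
- Empty inputs propagate as empty outputs (no strides → empty events →
  empty DMO report with a warning), never as errors.

## Problem sizes used in the test-suite

The validation suite uses 6 mixed-class training walks (≈ 40 strides
each), a 20-bout mixed-speed/mixed-staircase segmentation set, 1,000
noise-free strides for event timing, and a 100-stride mixed bout for
spatial recovery — sizes chosen so the whole suite exercises every code
path across all three stride types and speeds while remaining quick to
run on a laptop.

## Known limitations

- The error-state filter assumes piecewise-static orientation updates are
  available; recordings that never rest (no static start/end) degrade to
  best-effort forced updates.
- Yaw is unobservable without a magnetometer or heading model; absolute
  horizontal direction is arbitrary per subsequence (lengths and heights
  are unaffected).
- The threshold classifier has no ramp class: ramp strides count as level
  walking, and stair-vs-level confusion concentrates near the flattest
  geometry (13 cm / 7.6°), which sits closest to the thresholds.
- Single- vs double-step stair sub-classification is not implemented.
- The generator does not simulate pathological gait; applying the
  pipeline to impaired populations needs separate validation.
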