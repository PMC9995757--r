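---
title: "Methods: tilt estimation, activity recognition and fall-risk biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt estimation, activity recognition and fall-risk biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`nearfallr` implements a complete in-home monitoring pipeline for
movement-disorder patients wearing a five-sensor inertial array (chest,
both thighs, both shanks, 100 Hz): segment-tilt estimation, recognition
of ten daily-living activities including near-falls, behavioral
fall-risk biomarkers, and a multivariable model of prospective fall
frequency. This vignette is the package's account of the methods, the
parameters that matter, and the design choices that were genuinely
open.

## The sensor array and data model

Each sensor logs tri-axial acceleration (m/s^2) and angular rate
(rad/s); a magnetometer column is parsed but unused (heading is out of
scope). `assemble_session()` applies per-placement clock offsets,
intersects the five corrected time ranges and resamples every channel
by linear interpolation onto one uniform 100 Hz grid, with `t = 0` at
the start of the overlap. Clock offsets are accepted as inputs rather
than estimated: in the hardware deployment they come from a real-time
clock the sensors synchronize against while charging, and no estimation
procedure is defined here.

## Switched-gain tilt observer

Body-segment pitch (sagittal tilt) is observable two ways: from the
gravity direction in the accelerometer (reliable at rest, corrupted by
linear acceleration during movement) and by integrating the pitch gyro
(accurate over short horizons, drifting through bias). The observer
fuses the two with a regime-switched correction gain:

```
theta[k+1] = theta[k] + dt * (omega[k] - b[k]) + K_theta(k) * (theta_acc[k] - theta[k])
b[k+1]     = b[k] - K_b(k) * (theta_acc[k] - theta[k])
```

with `theta_acc = atan2(ax, az)`. While `| ||a|| - g |` stays within
the switch threshold (default 1.5 m/s^2) the accelerometer is trusted
(`K_theta = 0.02` per 10 ms step); during high dynamics the gain drops
to 0.002 and the estimate rides the gyro. The bias gain is tied at
`K_b = K_theta / 10`. These constants are fixed by design rather than
synthesized from a stability program: they were chosen once so that a
60 s sinusoidal benchmark (0.3 rad amplitude at 1 Hz, 0.05 rad/s bias,
default sensor noise) is tracked with RMSE below 2 degrees after a 5 s
burn-in and the bias is recovered to within 0.01 rad/s — properties the
test suite checks. Initialization uses the first accelerometer tilt
sample and zero bias. Only pitch is estimated, matching the in-plane
geometry of walking that the five-sensor placement exploits; full 3-D
orientation is a non-goal.

## Synthetic sessions: what the simulator does and does not emulate

Because no deposited recordings exist, the package carries a
first-class simulator. A random *activity script* draws segments from a
class mix until a target duration is reached, with a posture grammar:
entering `sit` always passes through `stand_to_sit`, leaving it through
`sit_to_stand`, and a `fall` is followed by sustained lying. Default
study conditions — the ones the tests and the acceptance script run
under — are:

* class mix: stand 0.23, walk 0.30, turn 0.14, sit 0.12, bend 0.08,
  lie-down 0.05, near-fall 0.06, fall 0.02 (falls and near-falls are
  rare events, but frequent enough here that a desk-scale session
  contains examples of every class);
* mean durations (s): stand 8, walk 12, turn 4 (movement-disorder
  patients turn slowly, in several short steps), sit 20, bend 3,
  lie-down 15, near-fall 1.8, fall 2, transfers 1.5 (clamped to
  0.5–5 s);
* sensor noise: accelerometer sd 0.3 m/s^2, gyro sd 0.02 rad/s, gyro
  bias uniform in ±0.05 rad/s, constant per session;
* one master seed drives every draw, so a session is bit-reproducible.

Canonical postures are defined in tilt space: standing is vertical
(all pitches ≈ 0 plus a 0.015 rad postural sway), sitting puts the
thighs at π/2, lying puts every segment at π/2. Gait is an anti-phase
left/right thigh-shank oscillation at a scripted cadence (walk
0.8–1.2 Hz, amplitudes 0.35/0.60 rad; turn 1.4–1.8 Hz, 0.15/0.28 rad,
plus a sustained yaw-rate pulse). A near-fall is a fast chest-pitch
excursion (Gaussian bump, sigma 0.2 s, peak 0.9 rad, peak rate above
2 rad/s) that recovers within 2 s, with a chest acceleration transient
of at least 5 m/s^2 above gravity; a fall is an excursion that ends at
π/2 and stays there. These near-fall thresholds are simulator
conventions — no quantitative inertial definition of a near-fall exists
in the field — and are stated here so they are not mistaken for
empirical claims.

The rendered physics is deliberately minimal: acceleration is gravity
plus an axial linear-acceleration envelope projected into the
segment-aligned sensor frame, and the gyro is the tilt derivative plus
bias. The simulator does *not* emulate soft-tissue artifact, sensor
mounting misalignment, magnetometers, or biomechanically exact gait;
passing tests on it demonstrates that the pipeline recovers what the
model encodes, not that the classifier would reach the same numbers on
patient data.

## Windowing and the classifier family

`window_session()` slices the session into 2.0 s windows with 0.5 s
stride — long enough to span a gait cycle or a transfer, short enough
to resolve transitions; the windowing of the original deployment is not
public, so this is a package choice. Per-step channels are the five
estimated tilt angles, the chest acceleration magnitude (near-fall
transients), and the chest yaw rate. The yaw channel is a deliberate
addition: turning is a transverse-plane motion that is invisible in
sagittal tilt, and without it turn/stand boundary windows are
undecidable in principle. Windows are labeled by the class covering the
largest fraction of them.

The CNN-LSTM is a compact sequence classifier implemented in
RcppArmadillo: windows are block-averaged to 25 Hz (activity dynamics
live well below 10 Hz, and a shorter sequence makes the recurrence
cheap), then conv1d(16, kernel 5) → maxpool(2) → conv1d(32, kernel 5) →
maxpool(2) → LSTM(64) → dense softmax. Training is Adam (lr 2e-3,
batch 64, gradient-norm clip 5) on class-weighted cross-entropy
(inverse-frequency weights, because near-falls and falls are rare), at
most 30 epochs with early stopping (patience 6) on a stratified 20%
validation split. All randomness — initialization, shuffling, the
split — flows from one integer seed, and the analytic gradients are
verified against finite differences in the test suite. The three
baselines (multinomial logistic regression, RBF-kernel SVM, decision
tree) are not sequence models; they see each window flattened to
per-channel mean, sd, min, max and dominant frequency.

Predicted probabilities break exact ties toward the earlier class in
canonical order (stand first). `smooth_and_segment()` median-filters
the label sequence (width 3) and merges runs into events; `near_fall`
and `fall` are exempt from both the filter and any minimum event
length, since a real near-fall can legitimately occupy a single window.

## Evaluation

Evaluation is per window (one-vs-rest): the published evaluation unit
("events") is ambiguous between windows and merged events, and the
printed totals are window-scale, so windows are the unit here.
`classification_stats()` computes TPR, TNR, PPV, NPV and ACC with `NA`
(never 0) on empty denominators. `roc_curve_auc()` sweeps thresholds
over the unique scores and integrates by the trapezoid rule, which
equals Mann–Whitney concordance with half-credit ties; the suite checks
that identity exhaustively on random instances. The bundled reference
table (`reference_activity_stats()`) carries the published counts and
printed statistics from the original video-validated deployment as a
regression fixture.

## Behavioral biomarkers

From a labeled event stream and the chest trace,
`compile_feature_table()` derives, per subject: near-fall count and
per-week frequency (per-week so the feature shares units with the
fall-frequency outcome); the number of ambulatory bouts (maximal unions
of walk/turn events with gaps ≤ 2 s — the bout definition is not
published, and the merge gap is config-exposed); sitting, walking and
lying fractions of monitored time; peak chest acceleration (per-day
maximum of `| ||a|| - g |`, averaged across days — mean was chosen as
the aggregator; median and max are defensible too); and `alpha_8`, the
continuous (Hill-type) maximum-likelihood power-law exponent of bout
durations above 8 s, undefined below 10 qualifying bouts. Weekly bout
totals are reported rather than per-day counts.

## The fall-frequency model

`correlation_screen()` ranks features by absolute Pearson correlation
with fall frequency (pairwise-complete observations; constant features
get `NA`). `fit_ols()` fits the fixed five-term model — near-fall
frequency, bout count, sitting frequency, UPDRS pull score, `alpha_8`,
plus intercept — by ordinary least squares on complete cases, with
`tidy()`/`glance()` accessors and `anova_summary()` producing the
total/model/residual decomposition. The published model summary implies
df_model = 5 and df_residual = 10, hence n = 16, although 17 subjects
returned diaries; the discrepancy is recorded, not resolved, and the
package takes the term list as given rather than re-deriving the "not
highly correlated" selection, whose criterion is unstated. No
multiple-testing correction is applied, matching the original analysis.
An independent pseudoinverse solver in the tests pins the
implementation to 1e-10, and a 2,000-replicate Monte-Carlo check
confirms 5% ± 2% type-I calibration of a true-zero coefficient at
n = 16.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale, chosen as the
package's own benchmark conditions: a 30-min training session and a
10-min held-out session for the end-to-end sensitivity check; 1,500 s
near-fall-enriched sessions across five seeds for the classifier AUC
ordering; 1e5 draws for exponent recovery; 2,000 replicates for the
OLS calibration. Gravity is 9.81 m/s^2 throughout. Event streams are
half-open `[start, end)` with session-relative times; uniform grids are
required by the observer and enforced (non-uniform input is an error,
not silently resampled). Undefined statistics are `NA` everywhere.

## Known limitations

* Simulator realism bounds what green tests mean for patient data
  (above); in particular the published cohort results — the ~0.69
  correlation of near-fall frequency with fall frequency, and the
  per-activity AUC table — require the real recordings and are out of
  scope.
* The observer estimates pitch only; activities distinguished by
  frontal-plane motion would need a richer state.
* Baseline featurization is a package choice; the original baselines'
  inputs are not public.
* The CNN-LSTM architecture is a faithful small instance of the
  published conv–LSTM–softmax design, not a reproduction of an exact
  (unpublished) architecture.
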