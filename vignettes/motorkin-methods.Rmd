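---
title: "Markerless motor assessment and its test-retest reliability: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markerless motor assessment and its test-retest reliability: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`motorkin` turns 20-joint markerless skeleton recordings of a
standardized six-maneuver motor protocol into 20 motor-function
variables, and quantifies how reliable those variables are when the
protocol is repeated. This vignette is the package's account of the
science: the measurement model, the synthetic motion generator that
stands in for the depth camera, the kinematic definitions, the
reliability statistics, and the numerical choices behind them.

## The measurement problem

Depth-camera ("markerless") motion capture estimates a virtual skeleton
— here the classic 20-joint model (hip center, spine, shoulder center,
head, and left/right shoulder, elbow, wrist, hand, hip, knee, ankle,
foot) — at a nominal 30 Hz, with joint-position errors of roughly
0.6–1.1 cm per axis. Whether motor variables computed from such data
are clinically usable is a reliability question: if a healthy subject
repeats the same protocol three times on one day, how consistently does
each variable rank subjects (relative reliability, ICC), and how large
is the trial-to-trial error in the variable's own units (absolute
reliability, SEM and CV)?

The protocol comprises six maneuvers, each announced by a scripted
bilateral arm-flap "greeting" that marks its start for segmentation:

* **RT** — resting stance, held ~10 s.
* **TT** — T position (arms abducted horizontally to 90°), held ~10 s.
* **FNT** — finger-to-nose: from the T position, alternately touch the
  nose and return, five repetitions per arm.
* **SST** — sideways step: step out as far as possible and return, five
  repetitions per leg.
* **T45** — monopodal balance: lift one foot sideways to a ~45°
  between-leg angle and hold ~10 s, each side.
* **CST** — chair-to-stand: sit down and stand up without using the
  arms, five repetitions, seat at knee height.

## The synthetic motion generator

No raw recordings of this protocol are publicly available, so the
package ships a simulator that is itself first-class, tested code: it
produces full protocol recordings with a ground-truth object holding
every programmed quantity, giving each downstream stage an exact oracle.

**Skeleton and pose.** A canonical standing skeleton is built from
stature-fraction anthropometry (hip center at 0.53 H, shoulder line at
0.82 H, etc.) in camera space: origin at the sensor, +y up, +z from the
camera toward the subject, the subject 2 m away. All joints except the
feet lie in one frontal plane, so frontal-plane rotations of a leg
chain about the pelvis produce exactly the programmed between-leg
angles — what makes 0.1°-level recovery checks meaningful.

**Trajectories.** Point-to-point movements (arm raises, reaches, steps,
sit-to-stand) follow minimum-jerk profiles (the 5th-order polynomial
with zero endpoint velocity and acceleration), the standard smooth
template for discrete human movements. The greeting is a raised-cosine
vertical oscillation of both wrists, by default 0.35 m peak, 2 cycles
at 1.5 Hz — the flap itself is not quantified in the protocol
description, so these are explicit, configurable parameters.

**Programmed values and calibration.** Apex step angles, the 45° hold,
the seated trunk tilt and the reach endpoints are imposed exactly in
the noise-free template. One subtlety: the T45 "airborne time" is
defined operationally as time with the lifted foot more than 5 cm above
its baseline, and the lift/lower transitions contribute to it. The
generator therefore shortens the apex hold by the analytic transition
surplus so that the *programmed airborne time* equals the scripted
10 s exactly; the ground truth records that value.

**Sensor model.** Noise is i.i.d. Gaussian per joint, frame and axis
with the published per-axis error SDs (x 6.5 mm, y 10.9 mm, z 5.7 mm)
as defaults. Nothing in the published error model describes temporal
correlation, so none is simulated — see "What the simulator does not
emulate".

**Variance injection.** A reliability study needs between-subject and
between-trial variance. The cohort generator draws demographics
matching a young adult cohort (age 24 ± 5 y, stature 170.7 ± 9.2 cm,
mass 72.9 ± 12.7 kg, ~62/38 male/female, half meeting the
150 min/week activity guideline) and gives each subject individual
programmed kinematics: subject-level normal deviations of step angle
(SD 3°), abduction angle (2.5°), trunk tilt (2°), reach duration
(0.12 s) and endpoint scatter (8 mm), with smaller trial-level
deviations (1.5°, 1.5°, 1°, 0.06 s, 3 mm). These SDs were fixed once,
at values that yield the moderate-to-high ICCs typical of this class of
instrument, and are user-overridable. A single master seed drives
independent named substreams (cohort, subject effects, trial effects,
sensor noise, bootstraps), so any source can be zeroed or replayed
alone and identical configurations reproduce byte-identical outputs.

Separately, `simulate_feature_matrix()` generates subjects × trials
matrices directly from the one-way random-effects model
$y_{ij} = \mu + b_i + e_{ij}$, $b_i \sim N(0, \sigma^2_b)$,
$e_{ij} \sim N(0, \sigma^2_w)$ — the exact population model whose
$\mathrm{ICC} = \sigma^2_b / (\sigma^2_b + \sigma^2_w)$ the estimators
target. This is the oracle for all estimator-recovery tests.

## Segmentation

**Greeting detection.** Both wrist y-trajectories are band-pass
filtered (0.5–3 Hz, 4th-order Butterworth, zero-phase `filtfilt`); an
event requires both envelopes to exceed `min_amplitude / 2` (default
0.05 m) for at least one cycle. Two refinements proved necessary. A
band-passed *step* (an arm lowering, a sit-down) is bipolar and can
cross the envelope threshold, so candidate events must also oscillate:
at least three sign alternations among supra-threshold samples of the
band-passed signal within 2.5 s of the onset. And because a zero-phase
filter pre-rings, the onset is refined on the raw trajectories as the
first frame where both wrists have risen `min_amplitude / 2` above a
local pre-event baseline; this lands 2–4 frames after the true onset,
well inside the 0.2 s tolerance used throughout. Candidates closer
than 0.5 s merge, keeping the earlier.

**Windows.** Maneuver *i* owns the window from the end of greeting *i*
to the start of greeting *i + 1* (the last window runs to the end of
the recording), labeled by the protocol order. Windows therefore
include still pauses; feature extraction narrows them (static holds to
their central 80%, the FNT/TT arm phases to the arms-raised run).

**Repetitions.** Dynamic maneuvers split on a scalar movement signal —
hand-to-nose distance (FNT), lateral ankle displacement (SST), pelvis
height (CST). The baseline is the signal's median over the window's
first 0.5 s; the band half-width is twice the local noise SD, floored
at 5% of the peak excursion so noise-free signals split cleanly;
out-of-band runs shorter than 0.2 s or peaking below 30% of the
maximum excursion are rejected. A count different from the expected
five per side is an explicit error and flags the trial invalid.

## Kinematic variables

Primary measures are per-frame joint-pair distances, angles at joint
triplets (arc cosine of the normalized dot product, degrees), and
angular velocities by central differences over the actual inter-frame
intervals. Positions are smoothed with a 5-frame moving average before
differentiation — at 30 Hz the published sensor noise would otherwise
dominate velocity estimates; ranges of motion ("point-cloud diameters",
the maximum pairwise distance of a joint's 3D trace) deliberately use
*raw* positions, because the noise floor is part of what that measure
reports. The nose landmark is not a tracked joint; its proxy is the
HEAD joint displaced 0.10 m along the subject's facing direction
(normal to the shoulder line), which keeps every feature invariant
under rotations about the vertical axis — a property the test suite
enforces with random rigid transforms. The single exception is the
frontal-plane trunk angle, defined in the camera's frontal plane as in
the original instrument, hence translation- but not rotation-invariant.

Per maneuver, the physical sub-measures are:

* **FNT** (per arm): mean and SD over repetitions of the minimum
  hand-to-nose distance; mean hand path speed per phase (to the nose
  and back); arm tilt below horizontal on return to the T position
  ("arm drop"), mean and SD.
* **RT + TT** (per hand, and for the head): point-cloud range and mean
  speed over the central 80% of each hold, averaged across the two
  conditions — involuntary hand movement and axial (head) stability.
* **SST** (per leg): apex between-leg angle (pelvis-to-ankle vectors)
  mean and SD; mean apex foot rise; percent of repetition time with the
  foot >2 cm above baseline.
* **T45** (per leg): airborne time (foot >5 cm above baseline); mean
  absolute deviation of the between-leg angle from the 45° target over
  the central airborne frames (0.6 s trimmed at each end, excluding
  the lift/lower transients); mean knee flexion of the lifted leg; head
  sway during the holds (axial balance).
* **CST**: 3D dispersion (RMS distance from the centroid) of the
  seated-extremum pelvis position across the five repetitions; mean
  vertical pelvis speed during the moving phases (frames with
  |dy/dt| > 0.05 m/s); maximum frontal-plane trunk angle.

The instrument's 20 variables group these sub-measures. The original
system's composite weights are not published, and its printed values
are unitless, so the package defines every multi-measure variable
(AccMov, VarMov, InvMov, MonSt_Bal, Stab_axial, Bal_axial,
Posture_CST) as an equal-weight mean of sub-measure z-scores,
standardized against a reference cohort — by default the input cohort
itself. Single-measure variables keep physical units: step amplitude in
degrees, reach speed in m/s, seated-position dispersion in meters, and
the asymmetry indices as the mean symmetric percent difference
$100\,|L - R| / \frac{L+R}{2}$ over their left/right pairs. Numeric
scales of the composites consequently do not match the original
instrument's (a non-goal); the physical sub-measures are written
alongside (`submeasures.csv`) so absolute reliability stays
interpretable. One naming choice was genuinely open: "axial balance"
is defined here as head sway during the two balance holds (its static
reading would duplicate axial stability exactly).

## Reliability statistics

For each variable, the subjects × trials matrix $X$ (rows with missing
trials dropped listwise, with a logged count) feeds:

**Repeated measures ANOVA.** The within-subject decomposition
$SS_{total} = SS_{subjects} + SS_{trials} + SS_{residual}$ with
$F = MS_{trials}/MS_{residual}$ on $(k-1, (n-1)(k-1))$ df tests for
systematic differences between attempts. Sphericity is checked with
Mauchly's W on the $k-1$ orthonormal contrasts of the trial covariance;
the p-value uses Box's chi-square series including the second-order
term (it agrees with `stats::mauchly.test` to well under a percent, and
the W statistic to 10 decimal places). When Mauchly rejects at
$\alpha = 0.05$, the F degrees of freedom are multiplied by the
Greenhouse–Geisser $\hat\varepsilon = \mathrm{tr}(T)^2 / ((k-1)
\mathrm{tr}(T^2))$ (clamped to $[1/(k-1), 1]$; exactly 1 when $k = 2$,
where the test is skipped) and the adjusted p is reported. Zero
residual variance is flagged degenerate with $F = \infty$, $p = 0$.

**ICC.** The default form is the one-way random single-measure
ICC(1,1) $= (MS_B - MS_W)/(MS_B + (k-1) MS_W)$ from the one-way
(subjects) decomposition — the form consistent with a one-factor
analysis; the two-way consistency form ICC(3,1) is available behind a
flag. The 95% CI is the exact F construction (Shrout–Fleiss): the
bounds of $MS_B/MS_W$ under the F distribution transformed through the
same ratio. Categories: < 0.50 poor, 0.50–0.69 moderate, 0.70–0.89
high, ≥ 0.90 excellent. The test suite verifies, on hundreds of random
matrices, that ICC(1,1) equals the method-of-moments variance ratio
$\hat\sigma^2_b/(\hat\sigma^2_b + \hat\sigma^2_w)$ to $10^{-10}$, and
that at the study design ($n = 29$, $k = 3$) the estimator's bias is
≤ 0.03 with CI coverage in [0.92, 0.98].

**SEM and CV.** $\mathrm{SEM} = \sqrt{MS_W}$ — the square root of the
intra-subject mean square from the one-way decomposition, in the
variable's units. $\mathrm{CV} = 100 \cdot \mathrm{SEM} / \bar{y}$ with
$\bar{y}$ the grand mean across all cells (equivalently the mean of the
attempt means — the reading of "SEM divided by the sum of the attempt
average" that yields the conventional CV; the package's
`cv_consistency_check()` verifies this reading lands inside the
two-decimal rounding envelope of a published reference table for 15 of
its 20 variables, logging the rest). CVs of 10% or less are flagged
acceptable. For cohort-standardized composites the grand mean is near
zero and a CV is not interpretable; the code warns and reports it
unflagged rather than silently dropping it.

**Effect size.** Attempt-to-attempt change standardized by the first
attempt's SD, $(\bar{y}_k - \bar{y}_1)/s_1$, with a seeded
bias-corrected bootstrap 90% CI (2000 resamples) — the
reference-trial standardization of the familiar spreadsheet approach,
re-derived here because its internals are not published. Bands:
< 0.41 small, 0.41–0.70 moderate, ≥ 0.70 large.

**Group comparisons.** The per-subject value is the mean of the three
attempts. Shapiro–Wilk within groups and Levene's test (mean-centered)
across groups, both at $\alpha = 0.05$, choose between Student's
t-test (equal variances) and the Wilcoxon–Mann–Whitney test; groups
under 3 subjects force the rank test with a warning. No multiplicity
correction is applied across the 20 variables, mirroring per-variable
reporting; a Holm adjustment is available behind a flag.

## Numerical choices, in one place

* Smoothing: 5-frame moving average before differentiation only;
  ranges use raw positions. Configurable off.
* Baselines: medians over the first 0.5 s of a window (feet, reach
  distance, pelvis height) — robust to onset transients.
* Static trims: central 80% of the hold; T45 hold statistics trim
  0.6 s of airborne transients at each end; airborne *time* is
  untrimmed.
* Repetition bands: 2 × local noise SD, floored at 5% of peak
  excursion; runs < 0.2 s or < 30% of peak rejected.
* Angles in degrees throughout; angle arguments clamped to [-1, 1]
  before `acos`; degenerate (zero-length) limb vectors give NaN with a
  warning.
* Tie-breaks: greeting candidates within 0.5 s keep the earlier;
  repetition apex is the frame of maximum excursion.
* Serialization: coordinates at 7 decimals (0.1 µm, far below sensor
  noise) so file round trips are value-exact.
* Seeds: every stochastic stage derives a 31-bit substream seed from
  the master seed and a stage label.

## What passing tests do and do not show

The simulator emulates smooth scripted kinematics, independent
per-frame Gaussian sensor noise, and subject/trial variance injected
through programmed movement parameters. It does **not** emulate:
self-occlusion and joint-tracking dropouts, temporally correlated or
distance-dependent sensor error, soft-tissue and posture idiosyncrasies,
fatigue or learning across series, or segmentation ambiguity from
sloppy greetings. Green tests therefore certify that the pipeline's
algorithms are correct and well-calibrated under the stated error
model — recovery of programmed kinematics to 0.1°, exact segmentation,
unbiased ICC/SEM with nominal coverage — not that the instrument is
reliable on real patients. The reliability statistics themselves are
distribution-level tools and apply to real feature tables unchanged.

Problem sizes used by the checks — chosen to match the study design
where one exists and kept modest elsewhere — are: 200 random matrices
for the estimator-oracle identity; 1000 replicates at $n=29, k=3$ per
ICC level for recovery; $10^4$ null simulations for the type-I rate;
10 subjects for geometric recovery; 50 subjects × 3 series for
segmentation; 10 subjects × 3 series end-to-end.

## Known limitations

* Composite variables are cohort-referenced z-scores: their absolute
  values depend on the reference cohort, and CVs for them are not
  meaningful (by construction; the sub-measures carry the units).
* The frontal trunk angle is camera-frame; subjects must face the
  camera, as the protocol prescribes.
* ICC form ambiguity is inherent to a one-factor description; both
  ICC(1,1) (default) and ICC(3,1) are provided, and they differ when
  systematic attempt effects exist.
* The greeting detector assumes the protocol's still pauses; back-to-
  back flapping within 0.5 s would merge.
* One greeting per maneuver (not per repetition) is assumed, following
  the protocol's "before each maneuver".
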