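---
title: "Phase-specific biomechanics of hand-to-mouth movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-specific biomechanics of hand-to-mouth movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htmphase)
```

## Scope

`htmphase` implements a complete analysis chain for phase-specific
biomechanical characterization of the standardized hand-to-mouth (HTM) task:
reach forward to a marked target, lift the hand to the lips, return to the
target, and return to the start. The chain runs from raw signals — seven
surface-EMG channels at 2000 Hz (brachioradialis BR, biceps brachii BB,
triceps brachii lateral head TRL, anterior/medial/posterior deltoid AD/MD/PD,
pectoralis major PM) and wrist position plus four joint angles at 400 Hz — to
group statistics and cross-validated impairment classification. Because
clinical recordings of this protocol are not publicly deposited, the package
ships a synthetic-cohort generator with known ground truth; the entire
pipeline is exercised and validated on that cohort.

## EMG to activation

Raw EMG is reduced to muscle activation $a_m(t) \in [0,1]$ by the standard
chain: zero-phase second-order Butterworth band-pass (30–450 Hz), full-wave
rectification, zero-phase second-order Butterworth low-pass (6 Hz), task-peak
normalization, recursive activation dynamics, and an exponential shaping
nonlinearity. The recursion is the canonical discrete two-pole filter

$$u(t) = \alpha\, e(t-d) - \beta_1 u(t-1) - \beta_2 u(t-2),$$

with unit DC gain ($\alpha - \beta_1 - \beta_2 = 1$) and a repeated real pole
placed so that the cascade's −3 dB point sits at 2 Hz at the working rate;
the electromechanical delay is $d = 40$ ms. Activation follows
$a = (e^{Au} - 1)/(e^{A} - 1)$ with shape $A \in [-3, 0)$, default −1.5.
These forms are the standard EMG-driven-modelling conventions; the package
keeps all of them configurable per muscle.

Task-peak normalization uses the maximum envelope across all five trials of a
subject, per channel. A consequence worth stating plainly: this normalization
is amplitude-blind — a uniform weakness that scales a whole channel cancels
out. Weakness therefore becomes observable downstream only through what it
does to the movement (slowing, reduced lift, compensation), which is also how
it manifests in normalized-EMG analyses of real patients unless maximal
voluntary contractions or calibrated maximal forces are available.

## Hill-type muscle mechanics

Muscle force follows
$F = F_{0m}\,(a\, f_l(\tilde l)\, f_v(\tilde v) + f_p(\tilde l))\cos\phi(\tilde l)$
with a Gaussian active force–length curve ($\exp(-(\tilde l - 1)^2/0.45)$), a
Hill force–velocity hyperbola with curvature $a/F_0 = 0.35$ (appropriate for
mixed-fiber arm muscles; the lengthening branch saturates at 1.4 with matched
slope at zero velocity), an exponential passive curve reaching $F_{0m}$ at
$\tilde l = 1.7$, and constant-thickness pennation
($\sin\phi \cdot \tilde l = \sin\phi_0$). The tendon is rigid; musculotendon
excursion about each joint is $-\int r(\theta)\,d\theta$ with per-muscle
quadratic moment-arm polynomials, and fiber velocity is normalized by
$10\, l_0$ per second. Fiber lengths are clamped to (0.4, 1.7) with a count
of clamped samples reported.

The default `F0m` values are *effective task-level maxima*, roughly 40% of
textbook maximal isometric forces (and lower still for the
abduction-adduction pair). The self-paced HTM task is gravity-dominated and
would recruit only 10–20% of textbook capacities; effective maxima make the
task span a realistic fraction of the activation range, which keeps task-peak
normalization well conditioned. Absolute force is not the object of study
here — phase contrasts and group contrasts are.

Net joint torques for shoulder and elbow flexion-extension come from planar
two-link inverse dynamics (Lagrangian double pendulum with gravity,
anthropometric segment parameters); abduction-adduction and
internal/external rotation have no two-link reference and use the summed
muscle-model torques (pointwise sums over contributors). A calibration routine
(`calibrate_muscles()`) adjusts per-muscle scale factors on `F0m` (±50%) and
the shared shape `A` by bounded L-BFGS-B minimization of the RMSE between
model and inverse-dynamics torques; tendon properties and optimal fiber
lengths stay fixed under the rigid-tendon simplification. On synthetic trials
with a known scale perturbation the routine recovers the perturbed scale
within a few percent when the error is evaluated over the unsupported
(airborne) portion of the movement.

## Phase segmentation

The four subphases are delimited by five timestamps found on 6 Hz low-passed
wrist kinematics: movement onset at a preset 5%-of-peak-speed threshold
(sustained for 150 ms, so noise spikes cannot trigger it), the two target
touches at sagittal-position extrema refined to the centre of their
zero-velocity dwell, the mouth touch at the vertical maximum co-occurring
with a speed minimum, and termination at a dynamic 2%-of-peak-speed
threshold followed by sustained rest. The reach polarity is inferred from the
first major sagittal excursion (configurable to a forced min/max), because
the later transport toward the mouth can displace the wrist farther in the
opposite direction. Dwell-region expansion bridges above-threshold
excursions shorter than 150 ms, which makes touch refinement robust to 4–8 Hz
tremor ripple. The algorithm is fully deterministic; a sidecar-table override
(`apply_boundary_overrides()`) mirrors a manual-correction step. Accuracy is
reported as pooled MAE/RMSE of the transition timings plus an absolute
agreement ICC(2,1).

## Features

Three metric families are evaluated per phase window (Phases I–IV and the
whole task), 26 metrics × 5 windows = 130 features, each participant's value
being the mean of trials 2–4:

* **Mechanical work** (J/kg): trapezoidal integral of power over the window,
  normalized by body mass. Muscles use force × fiber contraction velocity
  (concentric positive); joints use net torque × angular velocity, the
  standard joint-power analogue.
* **SPARC smoothness**: negative arc length of the magnitude spectrum of the
  windowed torque, normalized by its zero-frequency value, up to an adaptive
  cutoff (highest frequency below 10 Hz where the normalized magnitude still
  reaches 0.05; 4× zero padding; sub-bin interpolation of the crossing).
  Values are negative; closer to zero is smoother; the metric is invariant to
  amplitude scaling. Note that windowed torque has non-zero endpoints, so a
  spectral-leakage tail is part of the metric's behaviour on any real
  signal.
* **TCCI** (torque-based co-contraction index): each muscle torque is
  rectified and normalized by its own whole-task maximum; the index is the
  time-average of the pointwise minimum of the two normalized profiles,
  in [0, 1]. Pairs: AD/PD, MD/PM, TRL/BB, TRL/BR. Rectification is required
  to keep the stated [0, 1] range for antagonists whose signed torque is
  negative.

## Group statistics and classification

Every feature is compared between groups with Shapiro–Wilk routing (Welch
t-test when both groups pass at 0.05, Mann–Whitney U otherwise), summaries
formatted to match the routing, and Benjamini–Hochberg FDR adjustment within
each window family of 26 tests (a global policy is available). Spearman
correlations against the severity score are computed within the stroke group
for a fixed clinically interpretable subset of metrics.

Features with adjusted p < 0.05 enter five classifiers — SVM with a
quadratic polynomial kernel (QSVM), SVM with a Gaussian kernel (GSVM),
logistic regression (LR), a random-subspace ensemble of 30 linear
discriminants with subspace size ⌈d/2⌉ and majority voting (SD), and a single
linear discriminant (LD) — under seeded stratified 5-fold cross-validation.
Selection is performed on the full dataset before cross-validation,
replicating the reference procedure; this is optimistic, and the honest
alternative is nested selection inside each training fold. Per fold,
features are z-scored with training-fold statistics; SVM kernel scales use
the median heuristic on the training data; no hyperparameters are tuned.
Pooled test-fold predictions give one confusion matrix, precision, recall,
F1 and a rank-statistic AUC per model. With many significant features the
discriminant models become ill-posed at n = 40, so the pipeline caps the
classifier input at the 20 features with the smallest adjusted p.

## The synthetic cohort

`generate_cohort()` emulates 20 + 20 subjects × 5 trials of the acquisition.
Per trial, the wrist path is a chain of minimum-jerk segments
start → target → mouth → target → start with 100 ms zero-velocity dwells at
the touches and 0.5 s rest pads; the target sits at 80% of arm length.
Shoulder/elbow flexion-extension come from planar two-link inverse
kinematics; smooth abduction (the arm stays slightly abducted throughout,
with an extra bump during transport) and internal-rotation profiles complete
the four angles. Joint torque demand is computed by inverse dynamics, scaled
by a table-support factor (0.1 during rest pads and target dwells — the
table carries the arm), and distributed to agonists in proportion to their
instantaneous torque capacity net of passive forces. Antagonists receive
`coactivation_level` × the agonist drive plus a braking burst (0.5 × agonist
drive over the deceleration half of each transport segment, the triphasic
pattern of discrete movements); agonists then compensate the antagonist
torque so the net active torque equals the demand exactly. EMG is synthesized
as 30–450 Hz band-passed Gaussian noise (order 4, so out-of-band power stays
below 5%) amplitude-modulated by the per-channel normalized drive, advanced
by the 40 ms electromechanical delay, with a gain proportional to
`force_scale`.

Impairment is injected through four coupled subject-level parameters drawn
from a severity score (an FMUE-like integer, 21–55 for stroke subjects):

* `force_scale` (0.35–0.95, increasing with severity score) — weakness;
* `coactivation_level` (0.06–0.45, decreasing with score);
* `tremor_amplitude` (0.03–0.35 of peak speed, decreasing with score) —
  action tremor at 4–7 Hz, injected as a velocity ripple proportional to the
  instantaneous ideal speed (5–10 mm wrist displacement at moderate
  amplitudes, consistent with intention tremor);
* `duration_scale` (1.05–1.9) — slowing.

Weakness expresses itself kinematically through the documented head-to-hand
compensation: the effective mouth position drops and shifts forward in
proportion to `force_scale`, which reduces the elbow flexion excursion and
hence elbow and elbow-flexor work. Healthy subjects draw near-nominal
parameters (coactivation 0.03–0.08, tremor below 0.02, pace within 5%).
Trial-level jitter perturbs the target position (±8 mm), mouth height
(±5 mm) and pace (±4%). Measurement noise emulates drift-corrected IMU
residuals: 2 Hz band-limited drift (0.2 mm positions, 0.002 rad angles) plus
white noise (0.03 mm, 1e-4 rad). Everything derives from one integer seed;
regeneration is bit-identical.

### What the synthetic cohort does and does not show

The generator reproduces, with FDR-significant group effects in the right
direction at n = 20 + 20: elevated TCCI for AD/PD, TRL/BB and TRL/BR; reduced
elbow-F/E work magnitude in Phases II and III; reduced smoothness of the BB
and BR torques in Phase II and of several joint torques; negative Spearman
correlation between co-contraction and the severity score; and
cross-validated accuracy with phase-specific features at least as high as
with whole-task features. Two findings of real patient data are *not*
reproduced, and tests do not pretend otherwise. First, the MD/PM TCCI
elevation: after per-muscle task-peak normalization the pectoralis channel's
coactivation component sits near the channel noise floor (its task maximum is
dominated by the braking burst, which scales with the same agonist drive), so
the pairwise minimum barely responds to `coactivation_level` for this pair.
Second, reduced *elbow-joint* smoothness in Phase II: the compensatory range
reduction removes the deep-flexion torque sign reversal and genuinely smooths
the stroke elbow torque in this generator, so the tremor→smoothness link is
validated by a controlled experiment (tremor varied alone, everything else
fixed) rather than by that particular group contrast. More generally, passing
tests on this cohort demonstrate that the pipeline recovers effects whose
generating mechanism is present; they say nothing about effects driven by
mechanisms the generator does not model (trunk compensation, spasticity
dynamics, fatigue, electrode artifacts).

## Numerical choices

* Zero-phase filtering uses even-reflection end padding (half a second),
  since plain `filtfilt` leaves large end transients and odd reflection
  amplifies the local noise slope at a resting edge.
* Segmentation landmark searches run on 6 Hz low-passed position and on
  speed differentiated *after* filtering (differentiating raw noisy positions
  leaves a rectified-noise floor above the 2% rest threshold).
* SPARC interpolates the threshold crossing between spectral bins; with 4×
  padding the result agrees with a dense-grid quadrature of the arc length to
  about 2e-4 on smooth test signals.
* Work integrals share window endpoints between adjacent phases, so
  whole-task work equals the sum of the four phase works to machine
  precision.
* The activation recursion runs at the EMG rate and is decimated by 5 to the
  kinematic rate afterwards; after the 2 Hz dynamics this is alias-free.
* Ties in Spearman correlations use midranks (`exact = FALSE`); the AUC is
  the Mann–Whitney rank statistic with midranks.

## Problem sizes

The default study conditions are 20 + 20 subjects × 5 trials (≈ 5.7 s healthy
and up to ≈ 9 s impaired trials; 200 trials, ≈ 2.3 × 10^6 EMG samples per
channel group). A full pipeline run takes on the order of a minute on one
CPU; the test suite exercises the full-size cohort once and reuses it across
test files. The null-calibration study for the statistics stage uses 200
replicate null cohorts of the same dimensions at the feature-table level.

## Worked example

```{r example, eval = FALSE}
run <- run_pipeline(pipeline_config(n_per_group = 20, seed = 1))
print(run)
run$segmentation$mae          # ms, against generator ground truth
subset(run$comparisons, metric == "TCCI_AD_PD" & window == "Whole")
run$cv_phase                  # classifier report, phase-specific features
```
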