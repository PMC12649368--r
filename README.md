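# htmphase

Phase-specific biomechanical analysis of hand-to-mouth (HTM) upper-limb
movements, for movement scientists and neurorehabilitation researchers who
want objective, phase-resolved indicators of motor impairment from wearable
surface EMG and wrist/joint kinematics.

The HTM task — reach forward to a marked target, lift the hand to the lips,
return to the target, return to the start — is a standard paradigm for
assessing proximal upper-limb function after stroke. `htmphase` implements
the full chain from raw signals to group-level inference:

1. **EMG → activation**: 30–450 Hz band-pass, rectification, 6 Hz low-pass
   (all zero-phase second-order Butterworth), task-peak normalization, and
   activation dynamics `u(t) = α e(t−d) − β₁u(t−1) − β₂u(t−2)` (unit DC gain,
   2 Hz cutoff) followed by `a = (e^{Au} − 1)/(e^A − 1)`.
2. **Hill-type muscle mechanics**:
   `F = F₀ₘ (a·f_l(l̃)·f_v(ṽ) + f_p(l̃)) cos φ(l̃)`, signed moment arms
   `τ_m = r_m(θ) F_m`, net joint torques `τ_joint = Σ τ_m`, a planar two-link
   inverse-dynamics reference for shoulder/elbow flexion-extension, and a
   bounded calibration of maximal-force scales against the reference torques.
3. **Phase segmentation** of the movement into four subphases from wrist
   kinematics (speed thresholds, position extrema, dwell-centre refinement),
   deterministic, with MAE/RMSE/ICC evaluation against a reference.
4. **Features**: phase-windowed mechanical work `w = ∫ F v dt` (J/kg), SPARC
   torque smoothness (negative spectral arc length with adaptive cutoff), and
   a torque-based co-contraction index
   `TCCI = (1/Δt)∫ min(τ̂_ag, τ̂_ant) dt ∈ [0, 1]` for four muscle pairs —
   26 metrics × 5 windows per participant.
5. **Statistics**: Shapiro–Wilk-routed Welch-t / Mann–Whitney comparisons,
   Benjamini–Hochberg FDR per window family, Spearman correlations against a
   severity score.
6. **Classification**: five classifiers (QSVM, GSVM, LR, subspace
   discriminant, LD) under seeded stratified 5-fold cross-validation, with
   accuracy/precision/recall/F1 and rank-statistic AUC, comparing
   phase-specific against whole-task feature sets.

A seeded synthetic-cohort generator (`generate_cohort()`) emulates healthy
and stroke-like trials — four-phase minimum-jerk kinematics,
activation-consistent 7-channel EMG, weakness/coactivation/tremor/slowing
injections with known ground truth — so the whole pipeline runs and is
validated without any data download. See the methods vignette
(`vignettes/htm-phase-biomechanics.Rmd`) for the models, defaults and
limitations.

## Worked example

```r
library(htmphase)
run <- run_pipeline(pipeline_config(n_per_group = 20, seed = 1))
print(run)
```

```
Hand-to-mouth phase-specific biomechanics run
  participants: 40 (healthy=20, stroke=20)
  segmentation: MAE 5.2 ms, RMSE 6.9 ms, ICC 1.000
  significant features: 94 phase-specific, 24 whole-task
  cross-validated accuracy (phase-specific features):
    QSVM  1.000 (AUC 1.000)
    GSVM  1.000 (AUC 1.000)
    LR    1.000 (AUC 1.000)
    SD    1.000 (AUC 1.000)
    LD    1.000 (AUC 1.000)
```

Reading this: the segmentation recovered the generator's ground-truth phase
boundaries with a 5.2 ms mean absolute error and perfect test–retest
agreement; 94 of the 130 phase-windowed features separate the groups after
FDR correction (including elevated AD/PD and TRL/BB co-contraction, reduced
Phase II/III elbow work, and reduced Phase II elbow-flexor torque smoothness
for the stroke-like group); and the injected impairment is strong enough at
these study conditions that every classifier separates the groups perfectly.
Individual stages are available as plain functions (`emg_envelope()`,
`activation_dynamics()`, `hill_force()`, `inverse_dynamics_2link()`,
`segment_phases()`, `sparc()`, `tcci()`, `compare_groups()`,
`cross_validate()`, ...), and a thin command-line wrapper lives at
`inst/cli/htmphase.R`.

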