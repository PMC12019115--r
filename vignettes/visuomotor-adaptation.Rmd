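---
title: "Methods: simulating and analysing visuomotor rotation adaptation across visual contexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing visuomotor rotation adaptation across visual contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmadapt)
```

# The problem

When a fixed angular offset (a *visuomotor rotation*) is inserted between a
hand movement and its visual feedback, people gradually adapt: their reaches
deviate in the direction opposite the rotation until the cursor again lands on
the target. vmadapt implements an analysis pipeline for experiments that ask
whether this adaptation is bound to the *style* of visual feedback. Three
visual contexts share one input-to-goal mapping:

* **Point** — input displacements translate a cursor over a static scene
  (ordinary cursor control);
* **Look** — the cursor stays fixed at screen centre while input pans and
  tilts a camera, so the whole scene moves opposite to the Point cursor
  (first-person-shooter aiming);
* **Inverted Look** — Look with input gains negated, so pushing the input
  device forward tilts the view down.

The scientific leverage comes from *equating* the contexts: the same input
stream must place the cursor at the same position relative to the target in
every context, so context manipulations change only the visual motion, never
the required movement.

# Task geometry

Workspace lengths are in arbitrary units (au) with the screen 4 au tall;
targets sit on a ring of diameter 2 au at the four cardinal directions
(0°/90°/180°/270° = right/up/left/down, counter-clockwise positive from +x,
y up). A rotation of magnitude 30° is applied clockwise or counter-clockwise
(counterbalanced across participants); internally rotations are signed with
ccw positive.

The Look camera is modelled as a pinhole viewing the task plane at depth
`camera_distance` (default 8 au): a pan/tilt pose `(yaw, pitch)` places the
plane centre at screen offset `(-d tan yaw, -d tan pitch)`. At every sample
the pose is solved *exactly* so the scene offset equals minus the Point
cursor position, which makes the cursor-relative position of every task-plane
point identical across contexts by construction (the package's acceptance
test verifies agreement to 1e-9 au over random inputs and both rotation
directions). The default depth keeps poses below 8° over the 2 au workspace,
far from the gnomonic singularity at 90°; paths that would drive the pose
within 5° of the singularity raise a `geometry-overflow` error. In Look the
perturbation is applied to the camera update, in Point to the cursor — the
task-plane cursor channel is the same either way.

Two Inverted-Look conventions are supported: `both` axes negated (default)
and `vertical_only`. The default makes the analysis' 180° hand-angle
correction exact — adding 180° to an Inverted-Look hand angle re-expresses it
relative to the ideal aim location, and that correction commutes with the
sign flips used elsewhere only under the both-axes convention. The
`vertical_only` alternative matches the "forward looks down" phrasing of FPS
inversion; it is available in the configuration but is not the default
because it makes the 180° correction exact only for vertical targets.

During homing the cursor snaps to the start-point when strictly within
0.05 au. The boundary case (exactly 0.05 au) is treated as outside; no
derived measure depends on the boundary.

# Schedules and the time-limit staircase

`build_schedule()` reproduces the four designs: 680 trials (100 baseline /
480 rotation / 100 washout) in one context; 800 trials with paired baselines,
480 rotation trials in the trained context and a transfer phase run with the
rotation off (exp2a) or on (exp2b); and 760 trials in which a single (top)
target is trained in Point and generalization is probed in Look or Inverted
Look across 15 cycles of 3 probes + 15 top-up trials, bracketed by a matched
unperturbed baseline-generalization block. Cycled blocks visit each cardinal
target once per four trials in random order. Within each generalization
cycle, a lateral (0°/180°) probe precedes the top/bottom probes, with the top
target probed first in seven or eight of the 15 cycles.

Timed designs draw each trial's limit from a pair of interleaved 1-up/1-down
staircases (±30 ms per trial; initial limits 450/1050 ms for mouse and
780/1380 ms for trackpad), used equally within each block — the package picks
the less-used staircase and breaks ties randomly. For any observer whose
success probability increases with the allowed time, this rule converges to
~50% success; the simulation tests check a band of ±0.03 around 0.5 for
logistic observers with thresholds 500–900 ms.

# The synthetic cohort

The generator exists so every downstream stage is testable without external
data; its defaults are fixed to the study conditions and are not tuned per
analysis.

**Learner.** Each simulated participant carries a compensation state per
cardinal *hand* direction. On every trial the state decays by a retention
factor A; on trials with error feedback the state at each direction d is
incremented by `B * e * exp(-D(d, trial)^2 / (2 * gen_sigma^2))`, where `e`
is the residual error at the trial's planned hand direction and `D` the
angular distance between hand directions. The state is shared across
contexts — a single internal model — which is the mechanism under test.
With feedback at one direction this converges to `30 B / (1 - A + B)`
degrees of compensation.

Defaults A = 0.99, B = 0.1, `gen_sigma` = 30° were chosen once to match the
adaptation profile typical of online rotation studies: a four-target cohort
asymptotes at `30 B / (1 - A^4 + B)` ≈ 21.5° (within the 21–24° range such
experiments report) and a single-target cohort accumulates ≈ 10° over its
first ten rotation trials. The 30° tuning width is in the range reported for
generalization around an aiming direction. Motor noise is white angular
noise of 4° SD per trial. Jump starts (launches toward an uncued target 90°
away) occur with per-experiment default probabilities 0.10 / 0.05 / 0.016 —
higher under time pressure — and single-frame input glitches with
probability 0.004 per trial.

**Trajectories.** The hand follows a minimum-jerk radial profile of 1 au
along the planned direction (duration 0.4 s), followed from 65% of the
movement by a corrective sub-movement that brings the cursor onto the target,
which reproduces the corrective hooks seen early in rotation blocks and in
washout without touching the angle at peak speed. Samples are emitted at the
participant's frame rate (60/120/144 Hz) with ±10% uniform frame jitter.
Jump-started trials omit the corrective sub-movement: the movement was never
directed at the cued target. In designs with the online jump-start check the
aborted attempt is recorded (`outcome = "jump_start_repeat"`) and the trial
repeated in place, so completed trial counts always match the schedule.

**What the generator does not emulate.** No explicit-strategy component
(deliberately: only total learning is analysed, and the state-space learner
is the minimal process consistent with the observed curves), no reaction
times, no device differences beyond staircase initial limits, and no frame
drops longer than the jitter band. Because transfer in the generator is
complete by construction, generalization contrasts on synthetic cohorts are
an upper bound: passing tests show the pipeline measures what the generator
put in, not that real cohorts transfer fully. Likewise the learner treats
every trial as giving outward error feedback; return-reach unlearning is
represented only through the probe trials' ordinary updates.

# Preprocessing

Stages run in a fixed order, because the glitch criterion is defined on raw
frames: **glitch rejection → uniform resampling → zero-phase filtering**.

* *Glitches*: a trial is excluded when speed between consecutive raw frames
  changes by more than 40 au/s (strict inequality, with a 1e-9 relative
  guard for floating-point representation at the bound). Both the cursor and
  the raw input channel are checked, since in camera contexts the recorded
  channel identity is ambiguous; either channel alone can be selected.
* *Resampling*: linear interpolation onto a 100 Hz grid spanning the
  recorded range only (no extrapolation); linear interpolation is exact for
  affine signals and has the standard `(2 pi f dt)^2 / 8` amplitude error
  bound for band-limited ones.
* *Filtering*: a 2nd-order digital Butterworth (bilinear transform, −3 dB at
  15 Hz per pass) applied forward and backward, giving squared magnitude and
  zero net phase. Each channel is padded with an odd (rotational) reflection
  of `max(9 × order, 24)` samples and the padding removed afterwards; odd
  reflection preserves the signal's endpoint value and slope, which keeps
  startup transients out of the movement. Trials shorter than the pad are
  unanalyzable. Near the Nyquist rate the bilinear transform warps
  frequency, so the measured 30 Hz gain (≈ 0.018) sits below the analog
  two-pass value 1/(1+(30/15)^4) ≈ 0.059; the agreement checks are therefore
  stated in absolute amplitude (0.01/0.02/0.05 at 2/15/30 Hz), and at the
  15 Hz cutoff the digital design is exact by construction.

# Kinematic measures

The *hand angle at peak speed* is the signed angle between the start→target
line and the start→input-position line at the moment of peak radial speed,
computed from the raw input channel (which perturbations never touch);
radial speed uses central differences. The *take-off angle* is the same
quantity at the first crossing of a 0.2 au radius, with the angle linearly
interpolated between the bracketing samples; the first crossing (not the
last) is used because the online check must fire before much feedback is
available. Raw angles are ccw-positive; reported angles are sign-normalized
so positive always means "opposite the perturbation" (ccw-group angles are
negated; unperturbed trials use the participant's assigned direction so
probe angles share the group's convention). Inverted-Look angles then
receive the 180° correction; with the both-axes convention the order of
correction and sign flip is immaterial.

Jump starts are classified offline when *both* |peak-speed angle| and
|take-off angle| exceed 60°, and online from the take-off angle alone (so
offline implies online). Classification angles are measured relative to the
ideal aim location — on Inverted-Look trials the 180°-corrected angle —
otherwise every valid inverted probe would sit near 180°. The symmetric
threshold makes raw-versus-normalized classification equivalent.

# Aggregation

Trials in the cycled designs are grouped into consecutive cycles of four,
averaging valid trials only; a cycle with no valid trial is missing and
skipped (no imputation), and repeated trials replace their originals in
sequence. Analysis periods follow the published windows: last 10 baseline
cycles; first/last 10 cycles of the rotation, washout and transfer blocks;
first/last 10 *trials* of the single-target rotation block. Derived
measures: after-effect = early washout − late rotation; transfer = first 10
transfer cycles − late rotation; generalization probes are baseline-corrected
per participant × context × target against the matched unperturbed block and
labelled trained / untrained / lateral by their planned *hand* direction
(under Inverted Look the top-screen target is the untrained hand direction).
Lateral probes stay in the table but out of the trained/untrained contrast.
The mean of the last 5 top-up trials per generalization cycle is reported as
an asymptote check.

# Statistics

* `mixed_anova()` fits the standard mixed-design decomposition (participant
  error stratum) for one between × one within factor, reporting F, p and
  partial eta squared via `eta_p2 = F df1 / (F df1 + df2)`. A hand-written
  sums-of-squares oracle cross-checks it in the tests to 1e-8, and in the
  degenerate one-within-level case the between-groups F equals the squared
  pooled t.
* `emm_contrast()` is the between-group difference of marginal means at one
  within-level, tested as a pooled-variance two-sample t with
  `n1 + n2 - 2` degrees of freedom — the contrast the marginal-means
  follow-ups report.
* `t_tests()` uses Welch's correction for independent samples (group sizes
  here make the difference negligible) and guards degenerate zero-variance
  inputs. All tests are two-tailed at alpha = 0.05.
* `mixed_lm()` fits `value ~ cycle + (1 | participant)` by REML with
  Satterthwaite degrees of freedom (lmerTest); the intercept can be offset
  against a reference (e.g. asymptotic learning), and an inestimable random
  intercept falls back to a flagged fixed-effects fit.
* Bayes factors are BIC approximations, `exp((BIC0 - BIC1)/2)`, computed on
  participant means (between effects) or within-participant differences
  (within and interaction effects), and are labelled approximate: they are a
  transparent evidence summary, not a reproduction of default-prior Bayes
  factors from specific packages.

Null calibration is exercised in the acceptance tests: on no-perturbation
cohorts every reported test's type-I rate over 1,000 simulations must lie in
0.05 ± 0.02, and each adaptation measure's grand mean must fall within the
measure's own per-cohort standard error of zero.

# Problem sizes and numerical choices

Simulation-based tests use cohorts sized to make their statistical point:
clean-pipeline identity on a 2-participant full-trajectory cohort (every one
of 1,360 trials within 0.1° of its planned aim), parameter recovery on 50
cohorts of 30 learners, null calibration on 1,000 cycle-level cohorts of 30,
and the acceptance script runs 8 participants per group for the
full-trajectory first experiment and 6 per group elsewhere — enough for
stable group means (±0.5°) while the whole script reruns in about two
minutes. Angles are wrapped into (−180°, 180°] with the boundary mapped to
+180°; angle interpolation at the take-off radius is linear in angle, not
position, so equal-angle brackets interpolate exactly.

# Known limitations

Equivalence across contexts is enforced at the task-plane level of the
pinhole model, not rendered pixels; monitor size and cursor sensitivity are
outside the model (the studies this mirrors performed no such calibration
either). The deposited-data adapter is not included — the pipeline consumes
its own CSV schema, and `run_pipeline()` accepts externally supplied trial
and trajectory tables in that schema. Bayes factors are deliberately
approximate, and the generator's learner is a convenience for testing, not a
claim about participants.
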