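---
title: "Decoding vigilance: methods behind the momdecode pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding vigilance: methods behind the momdecode pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sustained monitoring for rare events is hard: when targets are infrequent,
people miss more of them and respond more slowly as time on task grows — the
*vigilance decrement*. `momdecode` implements a complete analysis pipeline
for a multiple-object monitoring (MOM) experiment designed to study this
effect with magnetoencephalography. In the task, dots travel along visible
trajectories from a screen corner towards a central object and normally
deflect away at a fixed *deflection point*; rare target dots fail to deflect
and must be intercepted with a button press before they collide. Blocks come
in two target-frequency regimes — *Active* (16 of the 32 cued-colour dots per
block are targets) and *Monitoring* (2 of 32) — and in each block only one
dot colour is task-relevant (*attended* vs *unattended*).

The pipeline covers five analyses:

1. **Behaviour** — per-block miss rates and correct RTs, block-wise Bayes
   factors for the Active-vs-Monitoring contrast, and the time-on-task ×
   target-frequency interaction that defines the vigilance decrement.
2. **Time-resolved decoding** of the *direction of approach* (left vs right
   entry corner) from all sensors at single time points, every 5 ms.
3. **Distance decoding**: the dot's ordinal *distance to object* (bin 15 =
   just appeared, bin 1 = at the deflection point) decoded from all 105
   pairwise classifiers over the 15 bins, assembled into a 15 × 15
   representational dissimilarity matrix (RDM) of accuracies.
4. **Informational connectivity**: the Spearman correlation between the
   105-entry RDM lower triangles of peri-frontal and peri-occipital sensor
   groups.
5. **Error analysis and prediction**: classifiers trained on correct trials
   only, tested on miss trials; and a second-level predictor that labels a
   trial correct/miss from its *accumulated accuracy* — the running mean of
   every pairwise classifier involving distances the dot has already
   traversed — with the decision threshold transferred across subjects
   leave-one-out.

Because real MEG recordings are large and external, the package ships a
synthetic-data generator that emulates the study conditions; every analysis
is exercised end to end on simulated cohorts.

## The generator

`generate_schedule()` reproduces the task book-keeping exactly: 110-s blocks
of 64 dots (32 per colour), 15 main blocks per condition (1920 dots in
total), 2 or 16 cued targets per block with the same number of non-cued
distractor events, onset-to-deflection 1226 ± 10 ms, deflection-to-collision
410 ± 10 ms, ISI 1660 ± 890 ms. Onsets are drawn from the ISI distribution
truncated at 100 ms and rescaled linearly when a draw would overrun the
block; the task's timing only enters the analysis through the per-dot
landmarks, so trajectories are represented by times, not pixels.

`simulate_behaviour()` is a deliberately simple outcome model: the miss
probability starts near 0.29 (Active) / 0.40 (Monitoring) in block 1, falls
by 0.03 per block to a 0.17 plateau under Active, and rises by 0.026 per
block under Monitoring; correct RTs are truncated-normal (250 ± 50 ms from
the deflection point) with a ±3 ms/block condition-signed trend; false
alarms occur at 3.5% per non-target dot, split across early presses, presses
on auto-deflecting events, and wrong-colour presses. These defaults were
fixed once so that a 21-subject cohort reproduces the qualitative
behavioural pattern (first-block rates near 30%/40%, a late-block
Monitoring-over-Active gap decisive by Bayes factor); they are parameters,
not fits to any particular dataset.

`simulate_epochs()` writes the task variables into −100..3000 ms epochs for
160 sensors at 1000 Hz (configurable). The signal has two parts, each a
box-car from 100 ms post-onset to the deflection point with 20-ms
half-cosine ramps:

* a **direction** term: one fixed smooth sensor pattern, opposite sign for
  the two entry corners, with per-trial amplitude jitter;
* a **distance** term: fifteen spatially ordered Gaussian-bump patterns
  centred on the posterior sensor quartile, indexed by the dot's
  *instantaneous* bin, with a mirrored anterior copy whose amplitude follows
  the attention-dependent frontal coupling.

Attended (cued-colour) trials are amplified by `attention_gain` (default
1.5). On miss trials the distance term is multiplied by `miss_attenuation`
(default 0.45) and the direction-amplitude jitter SD by
`miss_direction_noise_inflation` (default 3) — weaker task-relevant coding
and noisier task-irrelevant coding on errors. Sensor noise is white Gaussian
(`noise_sd`, default 10). The attenuation/noise defaults were calibrated
once so that per-trial mean distance-decoding accuracies centre near 0.60
for correct and 0.56 for miss trials on a default subject; after that they
were left alone.

What the generator does **not** emulate: temporally correlated sensor noise,
eye or cardiac artefacts, inter-subject head-position and topography
differences, epoch overlap correlations (epochs are generated independently
per dot even where the real task's epochs overlap), and post-deflection
visual differences between outcomes. Passing tests therefore demonstrate
that the *analysis machinery* is correct and recovers known ground truth;
they do not certify performance figures on real recordings.

## Decoding choices

All decoders are two-class LDA with a pooled covariance shrunk towards its
identity-scaled average. Shrinkage is the analytic Ledoit-Wolf intensity by
default (`shrinkage = "auto"`), exposed as a parameter; with 160-sensor
multi-sample feature vectors and a few dozen training trials per class, some
regularization is unavoidable. A tied discriminant score (exactly zero) is
assigned to the first class, deterministically.

Cross-validation is 10-fold and *trial-grouped*: every sample derived from a
trial carries the trial's fold, so train and test never share a trial — the
fold audit is asserted in the tests. Within each training fold the two
classes are equalized by seeded subsampling; fold accuracies are averaged
with equal weight. Class counts across the eight condition cells
(attention × frequency × early/late) are equalized by seeded subsampling to
the global minimum before condition comparisons.

Distance features: each trial's onset-to-deflection span is split into 15
equal time windows (constant dot speed makes equal time equal distance;
windows are computed per trial because deflection times vary by ±10 ms). A
sample on an exact window boundary belongs to the later window — the
nearer-object bin. At 200 Hz a window holds ~16 samples; `samples_per_bin`
(default 5) of them are retained by uniform within-window decimation, which
keeps the feature length at `sensors × samples_per_bin` for every trial and
matches the small per-window feature counts typical of this analysis.
Features are flattened sensor-major (all retained samples of sensor 1, then
sensor 2, ...). Left- and right-entry trials are pooled under shared
distance labels before pairwise decoding, so distance decoding cannot lean
on the direction signal (a property test decodes distance at chance from
direction-only synthetic data).

The direction decoder uses single-sample all-sensor features every 5 ms
(one sample at the 200 Hz analysis rate); the distance decoder uses the
windowed features above. Downsampling from the acquisition rate is a
windowed-sinc FIR low-pass (cutoff 80% of the target Nyquist, reflection
padding, exactly unit DC gain) followed by decimation that always retains
the first sample, so −100..3000 ms at 1000 Hz becomes 621 samples at 200 Hz.

## Error prediction

The correct-vs-miss generalization trains classifiers on correct attended
trials only and tests on held-out correct folds and on all miss trials,
using pre-deflection data only. The fold count is `round(n_correct /
n_miss)` (clamped to at least 2), so a held-out correct fold is about the
size of the miss set — the two test sets are comparable.

The outcome predictor splits correct trials 80/10/10 into train, validation
and test (every trial spans all 15 distance bins, so the split is
automatically balanced over distance classes); trains the 105 pairwise
classifiers on the training portion; and accumulates each test trial's 0/1
flags along the traversed distances. Each pair contributes the flag of the
trial's sample at the pair's larger distance, so the flag count at distance
`d` is `105 − choose(d−1, 2)`: 14 at distance 15, 27 at 14, ..., 105 at 1
(asserted for all `d`). A trial is labelled *miss* when its accumulated
accuracy falls strictly below `validation_mean(d) − m × validation_sd(d)`;
a trial exactly on the boundary counts as correct. Validation statistics
are computed per distance (a pooled option would blur the strong distance
dependence of the accumulated accuracy); the threshold multiple `m` is
swept over 0.1..4 in steps of 0.1, the within-subject optimum maximizes
accuracy averaged over distances (tied optima average their `m`), and the
multiple applied to a held-out subject is the mean of the other subjects'
optima — no within-subject circularity.

Prediction accuracy is reported as balanced accuracy (the mean of the
per-outcome hit rates). This equals, in expectation, accuracy after
subsampling to equal class counts, has chance level 0.5 regardless of the
correct/miss imbalance, and is deterministic.

## Bayes factors

`jzs_bf_ttest()` implements the default Bayes-factor t-test with the
Jeffreys-Zellner-Siow prior: a Cauchy prior of scale `r = sqrt(2)/2` on the
standardized effect, integrated by one-dimensional quadrature over the
inverse-gamma mixing parameter. It is deterministic, scale-invariant, and
verified in the tests against an independent reference implementation.
The original analysis describes a data-driven prior scale seeded by an
initial t-test; that procedure is under-specified, so the package uses the
fixed default scale and exposes `r`.

`bf_anova_effect()` is a full-vs-restricted model comparison for the
within-subject 2 × 2 × 2 design: every candidate model carries the subject
indicator as an additive random factor plus zero-centred g-priors on its
sum-to-zero condition effects (prior scale 0.5 for condition terms, 1 for
subject). Conditional on the per-term `g` parameters the marginal
likelihood is available in closed form (Jeffreys priors on the grand mean
and error variance integrate analytically); the `g`'s are integrated by
seeded Monte Carlo (4000 draws by default), with the same seed for the
full and restricted models so shared-term noise largely cancels. The
reported BF for an effect is BF(full)/BF(restricted), where the restricted
model drops exactly the term under evaluation. Evidence categories follow
the conventional thresholds: BF > 10 / > 3 strong / moderate for the
alternative, < 1/10 / < 1/3 for the null, otherwise insufficient.

`bf_vs_shuffled_null()` compares a cohort's observed accuracies against an
empirical null built from seeded label permutations (1000 by default) with
the two-sample JZS machinery. No multiple-testing correction is applied
across time points or distances; Bayes factors are reported pointwise.

## Problem sizes and determinism

Full-scale runs (1920 trials × 160 sensors × 21 subjects) are expensive, so
the shipped analyses use reduced sizes chosen once as representative: the
behavioural cohort runs the full 30-block design for 21 subjects; the
decoding cohorts use 10–24 sensors at 200 Hz, 4–10 blocks per condition and
10–14 trials per condition cell; the parameter-recovery suites use 21
subjects at 16 sensors. At these sizes every recovery contrast in the test
suite (attention gain, miss attenuation, vigilance slope, outcome
prediction) resolves decisively in the expected direction, and the whole
suite runs in minutes on one CPU.

Every random draw flows from named seeds derived by a documented integer
hash (`derive_seed(master, labels...)`); one master seed fans out per
subject and stage, identical configurations reproduce outputs byte for
byte, and the pipeline manifest records an MD5 hash per output file.

## Known limitations

* The generator's white sensor noise makes decoding SNR scale more cleanly
  with sensor count than real MEG noise would; absolute accuracies are not
  comparable to real-data values.
* The behaviour model treats miss probability as independent across targets
  given the block; it has no sequential (post-error) dynamics.
* The BF ANOVA's Monte-Carlo integration carries seed-dependent noise of a
  few percent on the BF scale; decisions at the 3 and 1/3 thresholds use
  effects far from the boundary in the tests.
* `read_epoch_dir()` defines this package's own plain container layout
  (JSON metadata + CSV labels + serialized array); it does not read
  third-party acquisition formats.
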