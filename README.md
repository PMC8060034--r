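# momdecode

Multivariate decoding and single-trial error prediction for
multiple-object monitoring (MOM) MEG experiments.

## What this package is for

When people monitor moving objects for rare critical events, performance
decays with time on task — the *vigilance decrement*. In the MOM paradigm,
dots travel along visible trajectories towards a central object and
normally deflect away at a fixed deflection point; rare target dots fail
to deflect and must be intercepted with a button press. Target frequency
(Active: 16/32 cued dots per block; Monitoring: 2/32), attention (cued vs
non-cued colour) and time on task (early vs late blocks) form a 2 × 2 × 2
within-subject design.

`momdecode` implements the complete analysis chain for such an experiment,
exercised end to end on synthetic cohorts:

* **Task and behaviour simulation** — exact MOM schedules (110-s blocks,
  64 dots, 1920 dots over 30 blocks; onset-to-deflection 1226 ± 10 ms;
  ISI 1660 ± 890 ms) and a configurable vigilance-decrement outcome model.
* **Synthetic epochs** — 160-sensor trials × sensors × samples arrays in
  which direction of approach, ordinal distance to the object, attention
  gain and miss-trial attenuation are written into the signal.
* **Decoding** — shrinkage-LDA with trial-grouped 10-fold cross-validation:
  time-resolved direction decoding every 5 ms, and all 105 pairwise
  distance classifiers (15 distance bins) assembled into an RDM
  (representational dissimilarity matrix of decoding accuracies).
* **Informational connectivity** — Spearman correlation of the 105-entry
  RDM lower triangles between peri-frontal and peri-occipital sensor
  groups, per condition and for correct vs miss trials (correct trials
  subsampled to the miss count, 100 repetitions).
* **Error analysis and prediction** — classifiers trained on correct
  trials only and tested on misses; per-trial accumulated accuracy

      A(d) = mean of all 0/1 classifier flags for pairs involving
             distances in {d, ..., 15},   N(d) = 105 − C(d−1, 2)

  thresholded at `validation_mean(d) − m · validation_sd(d)` with the
  multiple `m` (grid 0.1..4 by 0.1) transferred leave-one-subject-out.
* **Bayes-factor statistics** — JZS (Cauchy-prior) t-tests by quadrature,
  full-vs-restricted Bayes-factor ANOVA with g-priors and subject as a
  random factor, shuffled-label empirical nulls, and the 10 / 3 / 1/3 /
  1/10 evidence categories.

## Worked example

Simulate a 21-subject behavioural cohort and test the vigilance decrement:

```r
library(momdecode)

summaries <- lapply(1:21, function(s) {
  sch <- generate_schedule(task_config(), derive_seed(1, s, "schedule"))
  sch <- simulate_behaviour(sch, behaviour_model(), derive_seed(1, s, "behaviour"))
  summarize_behaviour(sch)
})
bw <- blockwise_condition_bf(summaries, "miss_rate")
behaviour_interaction_bf(summaries)$bf10
```

Running the shipped drivers prints, for one seeded cohort:

```
$ Rscript analysis/01_simulate_behaviour.R
block 1 miss rate:  Active 31%, Monitoring 43%
block 15 miss rate: Active 15%, Monitoring 74%
miss-rate contrast decisive (BF > 3) from block 2 onwards
time-on-task x target-frequency interaction: BF10 = 2.74e+03 (strong_alt)
```

Miss rates start high in both regimes, recover with practice when targets
are frequent (plateau near 15–17%), and climb steadily when targets are
rare — the behavioural signature of a vigilance decrement, decisively
supported by the block-wise and interaction Bayes factors.

```
$ Rscript analysis/02_decoding.R
direction decoding: 50.8% before onset, 73.3% from 100 ms to deflection
distance decoding (mean over 15 distances): attended 54.1%, unattended 50.4%
```

Direction of approach is at chance before the dot appears and strongly
decodable afterwards; distance information is present and amplified by
attention.

The `analysis/` directory holds the full sequence of drivers
(`01_simulate_behaviour.R` … `05_stats.R`), each a thin script over the
package functions that writes its tables under `results/`.

## Package layout

* `R/` — simulation (`task_config`, `behaviour_model`, `sensor_model`,
  `generate_schedule`, `simulate_behaviour`, `simulate_epochs`),
  preprocessing (`downsample`, `bin_distances`, `pool_directions`,
  `equalize_trial_counts`), decoding (`fit_lda`,
  `decode_direction_timecourse`, `decode_distance_pairwise`,
  `per_distance_accuracy`), connectivity (`group_rdm`,
  `informational_connectivity`, `connectivity_by_condition`), error
  pipeline (`train_correct_test_miss`,
  `single_trial_accuracy_distributions`, `split_correct_trials`,
  `accumulate_accuracy`, `sweep_thresholds`, `loso_predict`), statistics
  (`jzs_bf_ttest`, `bf_anova_effect`, `bf_vs_shuffled_null`,
  `interpret_bf`) and orchestration (`run_config`, `run_pipeline`,
  `write_epoch_dir`/`read_epoch_dir`).
* `analysis/` — numbered narrative drivers writing `results/`.
* `vignettes/monitoring-decoding.Rmd` — the methods vignette: models,
  assumptions, parameter choices, and what the synthetic cohorts do and do
  not show.
* `tests/testthat/` — unit, property and acceptance suites.
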