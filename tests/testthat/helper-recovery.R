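# scaled-down 21-subject recovery cohorts used by the acceptance suite.
# The contrast parameters under test (attention gain, miss attenuation,
# vigilance slope) keep their default / null values; only the problem size
# (sensors, blocks, trials per cell) is reduced for desk-scale runtime.

recovery_n_subjects <- 21L

# per-subject 2x2x2 cell accuracies for the attention BF ANOVA
attention_recovery_cohort <- function(attention_modulated, n_blocks = 4,
                                      per_cell = 12) {
  sm <- if (attention_modulated) {
    sensor_model(n_sensors = 16, fs_hz = 200, noise_sd = 5)
  } else {
    # attention-blind generator: unit gain and symmetric frontal coupling
    sensor_model(n_sensors = 16, fs_hz = 200, noise_sd = 5,
                 attention_gain = 1,
                 frontal_coupling_attended = 1, frontal_coupling_unattended = 1)
  }
  halves <- default_halves(n_blocks)
  tag <- if (attention_modulated) "mod" else "null"
  rows <- list()
  for (s in seq_len(recovery_n_subjects)) {
    cfg <- task_config(n_blocks_per_condition = n_blocks, practice_blocks = 1)
    sch <- simulate_behaviour(generate_schedule(cfg, derive_seed(s, "sch", tag)),
                              behaviour_model(), derive_seed(s, "beh", tag))
    half <- ifelse(sch$block %in% halves$early, "early",
                   ifelse(sch$block %in% halves$late, "late", NA))
    ok <- !sch$is_practice & sch$outcome %in% c("hit", "correct_reject", "none")
    cells <- split(which(ok), paste(sch$colour[ok], sch$condition[ok], half[ok]))
    sel <- unlist(lapply(seq_along(cells), function(i) {
      with_seed_test(derive_seed(s, "sel", tag, i),
                     sort(sample(cells[[i]], min(per_cell, length(cells[[i]])))))
    }))
    ep <- simulate_epochs(sch, sm, derive_seed(s, "ep", tag), trials = sort(sel),
                          early_blocks = halves$early, late_blocks = halves$late)
    bn <- pool_directions(bin_distances(ep, samples_per_bin = 3))
    for (attn in c(TRUE, FALSE)) for (fr in c("active", "monitoring")) {
      for (hf in c("early", "late")) {
        idx <- which(bn$labels$attended == attn & bn$labels$condition == fr &
                       bn$labels$epoch_half == hf)
        rdm <- decode_distance_pairwise(subset_binned(bn, idx), n_folds = 4,
                                        seed = derive_seed(s, "rdm", attn, fr, hf))
        rows[[length(rows) + 1]] <- data.frame(
          subject = sprintf("s%02d", s),
          attention = if (attn) "attended" else "unattended",
          frequency = fr, half = hf,
          value = mean(per_distance_accuracy(rdm)))
      }
    }
  }
  do.call(rbind, rows)
}

# per-subject pooled distance-binned sets (attended trials, miss-prone
# behaviour) for the correct-vs-miss and LOSO recovery analyses
miss_recovery_cohort <- function(attenuated, n_blocks = 4, max_correct = 100) {
  sm <- if (attenuated) {
    sensor_model(n_sensors = 16, fs_hz = 200, noise_sd = 5)
  } else {
    sensor_model(n_sensors = 16, fs_hz = 200, noise_sd = 5,
                 miss_attenuation = 1, miss_direction_noise_inflation = 1)
  }
  beh <- behaviour_model(base_miss_prob = 0.5, base_miss_active = 0.35,
                         vigilance_slope = 0.01, active_learning_slope = 0.01)
  lapply(seq_len(recovery_n_subjects), function(s) {
    cfg <- task_config(n_blocks_per_condition = n_blocks, practice_blocks = 1)
    sch <- simulate_behaviour(generate_schedule(cfg, derive_seed(s, "sch")),
                              beh, derive_seed(s, "beh"))
    att <- which(!sch$is_practice & sch$colour == "cued")
    miss <- att[sch$outcome[att] == "miss"]
    corr <- att[sch$outcome[att] %in% c("hit", "correct_reject")]
    corr <- with_seed_test(derive_seed(s, "sub"),
                           sort(sample(corr, min(max_correct, length(corr)))))
    ep <- simulate_epochs(sch, sm, derive_seed(s, "ep"),
                          trials = sort(c(miss, corr)))
    pool_directions(bin_distances(ep, samples_per_bin = 3))
  })
}
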