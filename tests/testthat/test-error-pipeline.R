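# a miss-prone behaviour model so small simulations contain enough misses
missy_model <- function() {
  behaviour_model(base_miss_prob = 0.5, base_miss_active = 0.4,
                  vigilance_slope = 0, active_learning_slope = 0)
}

test_that("accumulation counts obey N(d) = 105 - choose(d - 1, 2)", {
  pairs <- utils::combn(15, 2)
  flags <- rep(1, 105)
  for (d in 1:15) {
    res <- accumulate_accuracy(flags, pairs, d)
    expect_equal(res$n, 105 - choose(d - 1, 2))
    expect_equal(res$mean, 1)           # all-correct flags accumulate to 1
  }
  expect_equal(accumulate_accuracy(flags, pairs, 15)$n, 14)
  expect_equal(accumulate_accuracy(flags, pairs, 14)$n, 27)
  expect_equal(accumulate_accuracy(flags, pairs, 1)$n, 105)
  with_na <- flags
  with_na[which(pairs[2, ] == 15)[1]] <- NA
  expect_error(accumulate_accuracy(with_na, pairs, 15), "missing")
})

test_that("accumulation is monotone in the added flags", {
  pairs <- utils::combn(15, 2)
  with_seed_test(1, flags <- rbinom(105, 1, 0.6))
  tr <- momdecode:::accumulation_traces(matrix(flags, 1), pairs)
  # moving from d+1 to d adds flags: correct additions never lower the mean,
  # incorrect additions never raise it
  for (d in 14:1) {
    new <- flags[pairs[2, ] == d]
    if (length(new) == 0) next
    if (all(new == 1)) expect_gte(tr[1, d], tr[1, d + 1])
    if (all(new == 0)) expect_lte(tr[1, d], tr[1, d + 1])
  }
  # full trace stays in [0, 1] and ends at the grand mean
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(tr[1, 1], mean(flags))
})

test_that("correct trials split 80/10/10, disjoint and exhaustive", {
  trials <- 101:200
  sp <- split_correct_trials(trials, seed = 3)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$validation), 10)
  expect_equal(length(sp$test), 10)
  expect_setequal(c(sp$train, sp$validation, sp$test), trials)
  expect_length(intersect(sp$train, c(sp$validation, sp$test)), 0)
  expect_length(intersect(sp$validation, sp$test), 0)
  expect_identical(sp, split_correct_trials(trials, seed = 3))
  expect_error(split_correct_trials(1:15, 1), "at least 20")
})

test_that("threshold sweep matches a brute-force confusion-matrix recount", {
  with_seed_test(4, {
    val <- matrix(runif(20 * 15, 0.5, 0.8), 20)
    test <- matrix(runif(30 * 15, 0.3, 0.8), 30)
    outc <- sample(c("correct", "miss"), 30, replace = TRUE, prob = c(0.6, 0.4))
  })
  m_grid <- c(0.5, 1, 2)
  sw <- sweep_thresholds(val, test, outc, m_grid)
  for (mi in seq_along(m_grid)) {
    for (d in 1:15) {
      bound <- mean(val[, d]) - m_grid[mi] * sd(val[, d])
      pred <- ifelse(test[, d] < bound, "miss", "correct")
      tp <- sum(pred == "miss" & outc == "miss")
      tn <- sum(pred == "correct" & outc == "correct")
      bal <- 0.5 * (tp / sum(outc == "miss") + tn / sum(outc == "correct"))
      expect_equal(sw$accuracy[mi, d], bal)
    }
  }
})

test_that("threshold sweep limits behave as expected", {
  with_seed_test(5, {
    val <- matrix(rnorm(20 * 15, 0.7, 0.01), 20)
    corr <- matrix(rnorm(10 * 15, 0.7, 0.01), 10)
    miss <- matrix(rnorm(10 * 15, 0.4, 0.01), 10)
  })
  test <- rbind(corr, miss)
  outc <- rep(c("correct", "miss"), each = 10)
  sw <- sweep_thresholds(val, test, outc, m_grid = c(5, 1000))
  # separable traces: an intermediate multiple classifies perfectly
  expect_true(all(sw$accuracy[1, ] == 1))
  # an absurdly large multiple labels everything correct: balanced 0.5
  expect_true(all(sw$accuracy[2, ] == 0.5))

  # degenerate zero validation SD collapses the boundary onto the mean
  expect_message(sweep_thresholds(matrix(0.7, 5, 15), test, outc, 1),
                 "degenerate validation SD")
})

test_that("LOSO transfer averages other subjects' best multiples", {
  with_seed_test(6, {
    val <- matrix(rnorm(20 * 15, 0.7, 0.05), 20)
    test <- rbind(matrix(rnorm(12 * 15, 0.7, 0.05), 12),
                  matrix(rnorm(12 * 15, 0.5, 0.05), 12))
  })
  outc <- rep(c("correct", "miss"), each = 12)
  subj <- list(validation_traces = val, test_traces = test, test_outcomes = outc)
  # identical subjects: the transferred multiple equals the common best
  res <- loso_predict(list(subj, subj, subj), m_grid = seq(0.5, 3, 0.5))
  expect_equal(res$transfer_m, res$best_m)
  expect_equal(length(unique(res$best_m)), 1)
  expect_true(all(res$accuracy > 0.5))
  expect_error(loso_predict(list(subj, subj)), "at least 3 subjects")
})

test_that("classifiers trained on correct trials transfer worse to miss trials", {
  sub <- small_subject(31, n_blocks = 2, behaviour = missy_model(),
                       max_trials = 150, attended_only = TRUE)
  bn <- pool_directions(bin_distances(sub$epochs))
  gen <- train_correct_test_miss(bn, seed = 7)

  n_c <- length(gen$correct_trials); n_m <- length(gen$miss_trials)
  expect_gte(gen$n_folds, 2)
  expect_lte(abs(gen$n_folds - n_c / n_m), max(1, 0.5 * n_c / n_m))
  # default generator attenuates the distance signal on misses
  expect_gt(mean(gen$per_distance_correct), mean(gen$per_distance_miss))

  dist <- single_trial_accuracy_distributions(gen)
  expect_equal(length(dist$correct), n_c)
  expect_equal(length(dist$miss), n_m)
  expect_gt(dist$cohens_d, 0.3)

  # no miss trials at all: clean refusal
  no_miss <- subset_binned(bn, bn$labels$outcome != "miss")
  expect_error(train_correct_test_miss(no_miss), "no miss trials")
})

test_that("the null generator shows no correct-vs-miss difference", {
  sm <- small_sensors(miss_attenuation = 1, miss_direction_noise_inflation = 1)
  sub <- small_subject(32, n_blocks = 2, sensors = sm,
                       behaviour = missy_model(), max_trials = 150,
                       attended_only = TRUE)
  bn <- pool_directions(bin_distances(sub$epochs))
  gen <- train_correct_test_miss(bn, seed = 8)
  gap <- mean(gen$per_distance_correct) - mean(gen$per_distance_miss)
  expect_lt(abs(gap), 0.05)
  d <- single_trial_accuracy_distributions(gen)$cohens_d
  expect_lt(abs(d), 0.45)
})

test_that("Cohen's d matches its closed form and flags degenerate input", {
  with_seed_test(9, {
    a <- rnorm(5000, 0.60, 0.05)
    b <- rnorm(5000, 0.56, 0.05)
  })
  expect_equal(cohens_d(a, b), (mean(a) - mean(b)) / 0.05, tolerance = 0.06)
  expect_equal(cohens_d(a, b), 0.8, tolerance = 0.1)
  expect_equal(cohens_d(a, a), 0)

  gen <- list(flags_correct_hi = matrix(1, 1, 5), flags_correct_lo = matrix(1, 1, 5),
              flags_miss_hi = matrix(0, 3, 5), flags_miss_lo = matrix(0, 3, 5))
  expect_warning(res <- single_trial_accuracy_distributions(gen), "fewer than 2")
  expect_true(is.na(res$cohens_d))
})

test_that("prediction preparation audits leakage and supports false alarms", {
  sub <- small_subject(33, n_blocks = 2, behaviour = missy_model(),
                       max_trials = 160, attended_only = TRUE)
  bn <- pool_directions(bin_distances(sub$epochs))
  prep <- prepare_prediction_subject(bn, seed = 10)
  expect_equal(ncol(prep$validation_traces), 15)
  expect_equal(nrow(prep$test_traces), length(prep$test_outcomes))
  expect_true(all(prep$test_outcomes %in% c("correct", "miss")))
  expect_length(intersect(prep$split$train, prep$split$test), 0)

  fa <- prepare_prediction_subject(bn, seed = 10, outcome_filter = "false_alarm")
  expect_true(any(fa$test_outcomes == "miss"))   # error class labelled uniformly

  # early/late stratification restricts the analysis to that half
  early <- prepare_prediction_subject(bn, seed = 10, epoch_half = "early")
  n_early <- sum(bn$labels$epoch_half == "early", na.rm = TRUE)
  expect_lte(max(early$split$train), n_early)   # indices live in the subset
  expect_lt(nrow(early$test_traces), nrow(prep$test_traces))

  no_err <- subset_binned(bn, !(bn$labels$outcome %in% c(
    "false_alarm_early", "false_alarm_event", "false_alarm_wrong_colour")))
  expect_error(prepare_prediction_subject(no_err, outcome_filter = "false_alarm"),
               "no false_alarm trials")
})
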