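#' Correct-vs-miss generalization decoding
#'
#' Trains distance classifiers exclusively on correct attended trials and
#' tests them both on held-out correct trials (cross-validation) and on
#' all miss trials, using pre-deflection data only (the distance bins all
#' precede the deflection point by construction). The number of folds is
#' `round(n_correct / n_miss)` clamped to at least 2, so each held-out
#' correct fold is approximately the size of the miss set and the two test
#' sets are comparable.
#'
#' @param binned Pooled `distance_binned_set` (attended and both outcomes
#'   present; unattended trials are dropped).
#' @param seed Fold seed.
#' @param shrinkage LDA shrinkage.
#' @return List: `per_distance_correct` / `per_distance_miss` (15-vector
#'   accuracies), `rdm_correct` / `rdm_miss` matrices, per-trial flag
#'   matrices `flags_correct_hi/lo`, `flags_miss_hi/lo` (miss flags
#'   averaged over fold classifiers), `correct_trials`, `miss_trials`,
#'   `n_folds`.
#' @export
train_correct_test_miss <- function(binned, seed = 1L, shrinkage = "auto") {
  lab <- binned$labels
  att <- lab$attended
  is_miss <- att & lab$outcome == "miss"
  is_corr <- att & lab$outcome %in% c("hit", "correct_reject")
  corr <- which(is_corr); miss <- which(is_miss)
  if (length(miss) == 0) stop("no miss trials: correct-vs-miss analysis undefined")
  if (length(corr) < 4) stop("too few correct trials")

  n_folds <- max(2L, min(round(length(corr) / length(miss)),
                         floor(length(corr) / 2)))
  folds <- make_folds(length(corr), n_folds, derive_seed(seed, "cm-folds"))

  np <- choose(binned$n_bins, 2)
  fc_hi <- matrix(NA_real_, length(corr), np)
  fc_lo <- matrix(NA_real_, length(corr), np)
  fm_hi <- matrix(0, length(miss), np)
  fm_lo <- matrix(0, length(miss), np)
  acc_c <- matrix(NA_real_, np, n_folds)
  acc_m <- matrix(NA_real_, np, n_folds)
  pairs <- NULL

  for (f in seq_len(n_folds)) {
    tr <- corr[folds != f]
    te_c <- corr[folds == f]
    res_c <- pairwise_train_test(binned, tr, te_c, shrinkage)
    res_m <- pairwise_train_test(binned, tr, miss, shrinkage)
    pairs <- res_c$pairs
    fc_hi[folds == f, ] <- res_c$correct_hi
    fc_lo[folds == f, ] <- res_c$correct_lo
    fm_hi <- fm_hi + res_m$correct_hi / n_folds
    fm_lo <- fm_lo + res_m$correct_lo / n_folds
    acc_c[, f] <- colMeans(rbind(res_c$correct_hi, res_c$correct_lo))
    acc_m[, f] <- colMeans(rbind(res_m$correct_hi, res_m$correct_lo))
  }

  to_matrix <- function(pair_acc) {
    m <- matrix(NA_real_, binned$n_bins, binned$n_bins)
    for (k in seq_len(np)) {
      m[pairs[1, k], pairs[2, k]] <- pair_acc[k]
      m[pairs[2, k], pairs[1, k]] <- pair_acc[k]
    }
    m
  }
  rdm_c <- to_matrix(rowMeans(acc_c)); rdm_m <- to_matrix(rowMeans(acc_m))
  list(per_distance_correct = per_distance_accuracy(rdm_c),
       per_distance_miss = per_distance_accuracy(rdm_m),
       rdm_correct = rdm_c, rdm_miss = rdm_m, pairs = pairs,
       flags_correct_hi = fc_hi, flags_correct_lo = fc_lo,
       flags_miss_hi = fm_hi, flags_miss_lo = fm_lo,
       correct_trials = corr, miss_trials = miss, n_folds = n_folds)
}

#' Single-trial accuracy distributions and their Cohen's d
#'
#' Averages each trial's 0/1 classifier-correctness flags over all 105
#' pairwise classifiers (both of the trial's samples per pair) to one mean
#' accuracy per trial, and contrasts the correct-trial and miss-trial
#' distributions with Cohen's d (pooled SD).
#'
#' @param gen Output of [train_correct_test_miss()], or a list with
#'   elements `flags_correct_hi/lo` and `flags_miss_hi/lo`.
#' @return List: `correct` and `miss` per-trial mean accuracies,
#'   `cohens_d` (`NA` with a warning when either group has < 2 trials),
#'   group means.
#' @export
single_trial_accuracy_distributions <- function(gen) {
  acc_c <- rowMeans(cbind(gen$flags_correct_hi, gen$flags_correct_lo))
  acc_m <- rowMeans(cbind(gen$flags_miss_hi, gen$flags_miss_lo))
  d <- if (length(acc_c) < 2 || length(acc_m) < 2) {
    warning("fewer than 2 trials in an outcome group: Cohen's d undefined")
    NA_real_
  } else {
    cohens_d(acc_c, acc_m)
  }
  list(correct = acc_c, miss = acc_m, cohens_d = d,
       mean_correct = mean(acc_c), mean_miss = mean(acc_m))
}

#' Cohen's d with pooled standard deviation
#' @param a,b Numeric samples.
#' @return (mean(a) - mean(b)) / pooled SD.
#' @export
cohens_d <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp <- sqrt(((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Split correct trials into train / validation / test portions
#'
#' Random disjoint, exhaustive split (about 80/10/10 by default). Every
#' trial carries feature vectors for all 15 distance bins, so the split is
#' automatically balanced over distance classes.
#'
#' @param trials Vector of correct-trial indices (>= 20).
#' @param seed Integer seed.
#' @param props Proportions for train / validation / test (sum to 1).
#' @return List of index vectors `train`, `validation`, `test`.
#' @export
split_correct_trials <- function(trials, seed = 1L, props = c(0.8, 0.1, 0.1)) {
  stopifnot(abs(sum(props) - 1) < 1e-9)
  n <- length(trials)
  if (n < 20) stop("need at least 20 correct trials to split, got ", n)
  n_val <- max(1L, round(props[2] * n))
  n_test <- max(1L, round(props[3] * n))
  with_seed(seed, {
    perm <- sample(trials)
    list(train = sort(perm[seq_len(n - n_val - n_test)]),
         validation = sort(perm[n - n_val - n_test + seq_len(n_val)]),
         test = sort(perm[n - n_test + seq_len(n_test)]))
  })
}

#' Accumulated classifier accuracy at one distance
#'
#' The running evidence for one trial when the dot reaches distance `d`:
#' the mean of the 0/1 flags of every pairwise classifier whose pair
#' involves any distance already traversed (i.e. in `d..15`), each pair
#' contributing the flag of the trial's sample at the pair's larger
#' distance. The count obeys `N(d) = 105 - choose(d - 1, 2)`: 14 flags at
#' d = 15, 27 at d = 14, ..., 105 at d = 1.
#'
#' @param flags_hi Numeric vector of the trial's 105 higher-distance-sample
#'   flags (order matching `pairs`).
#' @param pairs 2 x 105 pair matrix (rows lo / hi) from the decoder.
#' @param d Distance (1..15).
#' @return List with `mean` and `n`.
#' @export
accumulate_accuracy <- function(flags_hi, pairs, d) {
  sel <- pairs[2, ] >= d
  if (anyNA(flags_hi[sel])) stop("missing classifier flags for distances >= ", d)
  list(mean = mean(flags_hi[sel]), n = sum(sel))
}

# full 15-point accumulation trace for a matrix of per-trial flags;
# returns trials x distance (column d = distance d)
accumulation_traces <- function(flags_hi, pairs, n_bins = 15L) {
  out <- vapply(seq_len(n_bins), function(d) {
    sel <- pairs[2, ] >= d
    rowMeans(flags_hi[, sel, drop = FALSE])
  }, numeric(nrow(flags_hi)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' Threshold sweep for second-level behavioural-outcome prediction
#'
#' For each threshold multiple `m` and distance `d`, a test trial is
#' labelled `miss` when its accumulated accuracy at `d` falls strictly
#' below `validation_mean(d) - m * validation_sd(d)` (a trial exactly on
#' the boundary counts as correct), and the prediction is scored against
#' the true outcomes as balanced accuracy (mean of the per-outcome hit
#' rates, so chance is 0.5 regardless of class imbalance).
#'
#' @param validation_traces Validation-trial accumulation traces
#'   (trials x 15, column `d` = distance `d`).
#' @param test_traces Test-trial traces (correct test portion plus all
#'   miss trials).
#' @param test_outcomes Character vector, `"correct"` or `"miss"`.
#' @param m_grid Threshold multiples (default 0.1..4 by 0.1).
#' @return List: `accuracy` (length(m_grid) x 15), `m_grid`,
#'   `validation_mean`, `validation_sd`.
#' @export
sweep_thresholds <- function(validation_traces, test_traces, test_outcomes,
                             m_grid = seq(0.1, 4, by = 0.1)) {
  stopifnot(ncol(validation_traces) == ncol(test_traces),
            nrow(test_traces) == length(test_outcomes))
  v_mean <- colMeans(validation_traces)
  v_sd <- apply(validation_traces, 2, sd)
  if (any(v_sd == 0)) {
    message("degenerate validation SD at ", sum(v_sd == 0),
            " distance(s); boundary equals the validation mean there")
  }
  acc <- matrix(NA_real_, length(m_grid), ncol(test_traces))
  for (mi in seq_along(m_grid)) {
    acc[mi, ] <- prediction_accuracy_at(m_grid[mi], v_mean, v_sd,
                                        test_traces, test_outcomes)
  }
  list(accuracy = acc, m_grid = m_grid, validation_mean = v_mean,
       validation_sd = v_sd)
}

# balanced accuracy of the threshold rule at multiple m, per distance
prediction_accuracy_at <- function(m, v_mean, v_sd, test_traces, test_outcomes) {
  is_miss <- test_outcomes == "miss"
  vapply(seq_len(ncol(test_traces)), function(d) {
    bound <- v_mean[d] - m * v_sd[d]
    pred_miss <- test_traces[, d] < bound
    sens <- mean(pred_miss[is_miss])
    spec <- mean(!pred_miss[!is_miss])
    (sens + spec) / 2
  }, numeric(1))
}

#' Leave-one-subject-out behavioural-outcome prediction
#'
#' For each held-out subject, the threshold multiple is the mean of the
#' best-performing multiples of all other subjects (best = maximizing the
#' sweep accuracy averaged over distances; tied maxima average their `m`
#' values), which avoids circularity; that transferred multiple is then
#' applied to the held-out subject's test trials.
#'
#' @param subject_sweeps List (>= 3) of per-subject lists with
#'   `validation_traces`, `test_traces`, `test_outcomes`
#'   (see [sweep_thresholds()]).
#' @param m_grid Threshold multiples.
#' @return List: `accuracy` (subjects x 15 at the transferred multiple),
#'   `best_m` (per-subject within-subject optimum), `transfer_m`
#'   (per-subject LOSO multiple), `predicted` (per-subject list of
#'   predicted labels at `transfer_m`, trials x 15 logical miss matrix).
#' @export
loso_predict <- function(subject_sweeps, m_grid = seq(0.1, 4, by = 0.1)) {
  ns <- length(subject_sweeps)
  if (ns < 3) stop("leave-one-subject-out transfer needs at least 3 subjects")
  sweeps <- lapply(subject_sweeps, function(s) {
    sweep_thresholds(s$validation_traces, s$test_traces, s$test_outcomes, m_grid)
  })
  best_m <- vapply(sweeps, function(sw) {
    avg <- rowMeans(sw$accuracy)
    mean(sw$m_grid[avg == max(avg)])    # ties: average the tied multiples
  }, numeric(1))
  transfer_m <- vapply(seq_len(ns), function(s) mean(best_m[-s]), numeric(1))

  nd <- ncol(sweeps[[1]]$accuracy)
  accuracy <- matrix(NA_real_, ns, nd)
  predicted <- vector("list", ns)
  for (s in seq_len(ns)) {
    sw <- sweeps[[s]]
    accuracy[s, ] <- prediction_accuracy_at(transfer_m[s], sw$validation_mean,
                                            sw$validation_sd,
                                            subject_sweeps[[s]]$test_traces,
                                            subject_sweeps[[s]]$test_outcomes)
    bound <- matrix(sw$validation_mean, nrow(subject_sweeps[[s]]$test_traces),
                    nd, byrow = TRUE) -
      transfer_m[s] * matrix(sw$validation_sd, nrow(subject_sweeps[[s]]$test_traces),
                             nd, byrow = TRUE)
    predicted[[s]] <- subject_sweeps[[s]]$test_traces < bound
  }
  list(accuracy = accuracy, best_m = best_m, transfer_m = transfer_m,
       predicted = predicted)
}

#' Build one subject's error-prediction dataset
#'
#' Runs the full first level for one subject: splits attended correct
#' trials 80/10/10, trains the 105 pairwise classifiers on the training
#' portion, tests them on the validation portion and on the test portion
#' plus all miss trials, and accumulates the per-trial flags into
#' 15-point traces.
#'
#' @param binned Pooled `distance_binned_set`.
#' @param seed Integer seed (split and fit are deterministic given it).
#' @param shrinkage LDA shrinkage.
#' @param outcome_filter Error class to contrast with correct trials:
#'   `"miss"` (default) or `"false_alarm"` (all three false-alarm types
#'   pooled).
#' @param epoch_half Optional `"early"` or `"late"` to stratify the whole
#'   analysis by time on task.
#' @return List with `validation_traces`, `test_traces`, `test_outcomes`,
#'   `split`, `pairs` — the input expected by [loso_predict()].
#' @export
prepare_prediction_subject <- function(binned, seed = 1L, shrinkage = "auto",
                                       outcome_filter = c("miss", "false_alarm"),
                                       epoch_half = NULL) {
  outcome_filter <- match.arg(outcome_filter)
  if (!is.null(epoch_half)) {
    epoch_half <- match.arg(epoch_half, c("early", "late"))
    keep <- !is.na(binned$labels$epoch_half) & binned$labels$epoch_half == epoch_half
    binned <- subset_binned(binned, keep)
  }
  lab <- binned$labels
  err_lv <- if (outcome_filter == "miss") "miss" else
    c("false_alarm_early", "false_alarm_event", "false_alarm_wrong_colour")
  corr <- which(lab$attended & lab$outcome %in% c("hit", "correct_reject"))
  err <- which(lab$attended & lab$outcome %in% err_lv)
  if (length(err) == 0) stop("no ", outcome_filter, " trials to contrast with correct trials")

  split <- split_correct_trials(corr, derive_seed(seed, "split"))
  res_val <- pairwise_train_test(binned, split$train, split$validation, shrinkage)
  test_all <- c(split$test, err)
  res_te <- pairwise_train_test(binned, split$train, test_all, shrinkage)

  # leakage audit: first-level training and validation never see test/miss ids
  stopifnot(length(intersect(split$train, test_all)) == 0,
            length(intersect(split$validation, test_all)) == 0)

  list(validation_traces = accumulation_traces(res_val$correct_hi, res_val$pairs,
                                               binned$n_bins),
       test_traces = accumulation_traces(res_te$correct_hi, res_te$pairs,
                                         binned$n_bins),
       test_outcomes = c(rep("correct", length(split$test)),
                         rep("miss", length(err))),
       split = split, pairs = res_te$pairs)
}
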