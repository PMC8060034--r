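#' Time-resolved direction-of-approach decoding
#'
#' Decodes the dot's entry corner (left vs right) from all sensors at
#' single time points, every `time_step_ms` across the epoch, with
#' trial-grouped k-fold cross-validation. Within each fold's training set
#' the two classes are equalized by seeded subsampling; fold accuracies
#' are averaged with equal weight.
#'
#' @param epochs An [epoch_set()].
#' @param n_folds Folds (default 10).
#' @param seed Seed for fold allocation and within-fold equalization.
#' @param time_step_ms Decoding step; must be a multiple of the sample
#'   step (5 ms at 200 Hz means every sample).
#' @param y Optional label override (e.g. permuted labels for an empirical
#'   null); defaults to `labels$direction`.
#' @param shrinkage Passed to the LDA fit.
#' @return List with `time_ms`, `accuracy` (per time step, in \[0, 1\]),
#'   `n_trials_per_class`, `fold_of_trial`.
#' @export
decode_direction_timecourse <- function(epochs, n_folds = 10L, seed = 1L,
                                        time_step_ms = 5, y = NULL,
                                        shrinkage = "auto") {
  if (is.null(y)) y <- epochs$labels$direction
  classes <- unique(y)
  if (length(classes) != 2) stop("direction decoding needs exactly two classes")
  y01 <- as.integer(y == classes[2])
  n <- n_trials(epochs)
  folds <- make_folds(n, n_folds, derive_seed(seed, "folds"))

  step <- 1000 / epochs$fs_hz
  stride <- time_step_ms / step
  if (abs(stride - round(stride)) > 1e-9 || stride < 1) {
    stop("time_step_ms must be a positive multiple of the sample step (", step, " ms)")
  }
  t_idx <- seq(1L, length(epochs$time_ms), by = as.integer(round(stride)))

  fold_sets <- lapply(seq_len(n_folds), function(f) {
    tr <- which(folds != f)
    list(tr = equalize_classes(tr, y01[tr], derive_seed(seed, "eq", f)),
         te = which(folds == f))
  })
  acc <- matrix(NA_real_, length(t_idx), n_folds)
  for (ti in seq_along(t_idx)) {
    xt <- epochs$data[, , t_idx[ti], drop = TRUE]
    if (is.null(dim(xt))) xt <- matrix(xt, ncol = 1)
    for (f in seq_len(n_folds)) {
      tr <- fold_sets[[f]]$tr; te <- fold_sets[[f]]$te
      if (length(unique(y01[tr])) < 2 || length(te) == 0) next
      ok <- lda_train_correct(xt[tr, , drop = FALSE], y01[tr],
                              xt[te, , drop = FALSE], y01[te], shrinkage)
      acc[ti, f] <- mean(ok)
    }
  }
  list(time_ms = epochs$time_ms[t_idx], accuracy = rowMeans(acc, na.rm = TRUE),
       n_trials_per_class = table(y), fold_of_trial = folds)
}

# subsample the larger class so both classes have equal training counts
equalize_classes <- function(idx, y01, seed) {
  i0 <- idx[y01 == 0L]; i1 <- idx[y01 == 1L]
  m <- min(length(i0), length(i1))
  with_seed(seed, sort(c(sample(i0, m), sample(i1, m))))
}

#' All-pairs distance decoding (RDM)
#'
#' Trains and tests a shrinkage-LDA classifier for each unordered pair of
#' the 15 distance bins (105 pairs), with trial-grouped k-fold
#' cross-validation: a trial's bin-`i` and bin-`j` feature vectors always
#' share the trial's fold, so train and test never mix samples of one
#' trial. Per-trial 0/1 correctness is retained for both of the trial's
#' samples in each pair (needed by the error-prediction pipeline).
#'
#' @param binned A direction-pooled `distance_binned_set`
#'   (see [pool_directions()]).
#' @param n_folds Folds (default 10).
#' @param seed Seed for fold allocation.
#' @param shrinkage LDA shrinkage.
#' @return An `rdm` object: `matrix` (15 x 15 symmetric accuracies, `NA`
#'   diagonal), `pairs` (2 x 105, rows lo/hi), `correct_hi`/`correct_lo`
#'   (trials x 105 correctness of the trial's higher-/lower-distance
#'   sample), `fold_of_trial`.
#' @export
decode_distance_pairwise <- function(binned, n_folds = 10L, seed = 1L,
                                     shrinkage = "auto") {
  stopifnot(inherits(binned, "distance_binned_set"))
  if (!binned$pooled) stop("pool directions first (pool_directions)")
  n <- dim(binned$features)[1]
  folds <- make_folds(n, n_folds, derive_seed(seed, "folds"))
  rdm_from_folds(binned, folds, shrinkage)
}

# core pairwise CV given a per-trial fold assignment
rdm_from_folds <- function(binned, folds, shrinkage = "auto") {
  nb <- binned$n_bins
  n <- dim(binned$features)[1]
  pairs <- utils::combn(nb, 2L)           # row 1 = lo, row 2 = hi
  np <- ncol(pairs)
  correct_hi <- matrix(NA_real_, n, np)
  correct_lo <- matrix(NA_real_, n, np)
  n_folds <- max(folds)
  acc <- matrix(NA_real_, np, n_folds)

  for (k in seq_len(np)) {
    lo <- pairs[1, k]; hi <- pairs[2, k]
    xlo <- binned$features[, lo, , drop = TRUE]
    xhi <- binned$features[, hi, , drop = TRUE]
    if (n == 1L) { xlo <- matrix(xlo, 1); xhi <- matrix(xhi, 1) }
    for (f in seq_len(n_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(tr) < 4 || length(te) == 0) {
        stop("pair ", lo, " vs ", hi, ": empty or too-small train/test fold")
      }
      xtr <- rbind(xhi[tr, , drop = FALSE], xlo[tr, , drop = FALSE])
      ytr <- rep(c(0L, 1L), each = length(tr))      # 0 = hi class
      xte <- rbind(xhi[te, , drop = FALSE], xlo[te, , drop = FALSE])
      yte <- rep(c(0L, 1L), each = length(te))
      ok <- lda_train_correct(xtr, ytr, xte, yte, shrinkage)
      correct_hi[te, k] <- ok[seq_along(te)]
      correct_lo[te, k] <- ok[length(te) + seq_along(te)]
      acc[k, f] <- mean(ok)
    }
  }
  mat <- matrix(NA_real_, nb, nb)
  pair_acc <- rowMeans(acc)
  for (k in seq_len(np)) {
    mat[pairs[1, k], pairs[2, k]] <- pair_acc[k]
    mat[pairs[2, k], pairs[1, k]] <- pair_acc[k]
  }
  structure(list(matrix = mat, pairs = pairs, pair_accuracy = pair_acc,
                 correct_hi = correct_hi, correct_lo = correct_lo,
                 fold_of_trial = folds, n_bins = nb),
            class = "rdm")
}

#' Per-distance decoding accuracy from an RDM
#'
#' Element `d` is the mean of the 14 pairwise accuracies involving
#' distance `d` (e.g. distance 15 averages 15-vs-14 down to 15-vs-1).
#'
#' @param rdm An `rdm` (or a plain symmetric matrix with `NA` diagonal).
#' @return Numeric vector of length `n_bins`.
#' @export
per_distance_accuracy <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else rdm
  rowMeans(m, na.rm = TRUE)
}

#' Lower triangle of an RDM
#' @param rdm An `rdm` or matrix.
#' @return The 105 below-diagonal entries, column-major.
#' @export
rdm_lower_triangle <- function(rdm) {
  m <- if (inherits(rdm, "rdm")) rdm$matrix else rdm
  m[lower.tri(m)]
}

# Pairwise classifiers trained on explicit training trials and applied to
# explicit test trials (no CV): returns per-test-trial correctness for
# both samples of every pair. Used by the correct-vs-miss generalization
# and the behavioural-error prediction pipeline.
pairwise_train_test <- function(binned, train_trials, test_trials,
                                shrinkage = "auto") {
  nb <- binned$n_bins
  pairs <- utils::combn(nb, 2L)
  np <- ncol(pairs)
  nte <- length(test_trials)
  correct_hi <- matrix(NA_real_, nte, np)
  correct_lo <- matrix(NA_real_, nte, np)
  for (k in seq_len(np)) {
    lo <- pairs[1, k]; hi <- pairs[2, k]
    xtr <- rbind(binned$features[train_trials, hi, , drop = TRUE],
                 binned$features[train_trials, lo, , drop = TRUE])
    ytr <- rep(c(0L, 1L), each = length(train_trials))
    xte <- rbind(binned$features[test_trials, hi, , drop = TRUE],
                 binned$features[test_trials, lo, , drop = TRUE])
    if (length(test_trials) == 1L) xte <- rbind(
      matrix(binned$features[test_trials, hi, ], 1),
      matrix(binned$features[test_trials, lo, ], 1))
    yte <- rep(c(0L, 1L), each = nte)
    ok <- lda_train_correct(xtr, ytr, xte, yte, shrinkage)
    correct_hi[, k] <- ok[seq_len(nte)]
    correct_lo[, k] <- ok[nte + seq_len(nte)]
  }
  list(pairs = pairs, correct_hi = correct_hi, correct_lo = correct_lo,
       test_trials = test_trials)
}
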