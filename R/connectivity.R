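#' Distance RDM restricted to a sensor group
#'
#' Identical procedure to [decode_distance_pairwise()], using only the
#' group's sensors as features. With `group = all` sensors this reproduces
#' the whole-head RDM (same fold seed, same result).
#'
#' @param binned A pooled `distance_binned_set`.
#' @param group Sensor index vector (non-empty).
#' @param n_folds,seed,shrinkage As in [decode_distance_pairwise()].
#' @return An `rdm`.
#' @export
group_rdm <- function(binned, group, n_folds = 10L, seed = 1L, shrinkage = "auto") {
  if (length(group) == 0) stop("empty sensor group")
  decode_distance_pairwise(subset_sensors_binned(binned, group),
                           n_folds = n_folds, seed = seed, shrinkage = shrinkage)
}

#' Informational connectivity between two RDMs
#'
#' Spearman rank correlation of the two 105-entry lower triangles: the
#' degree to which two sensor groups share the same structure of pairwise
#' distance discriminability. Invariant to any strictly increasing
#' transform of either RDM.
#'
#' @param rdm_a,rdm_b `rdm` objects or 15 x 15 matrices.
#' @return List with `rho` (`NA` and `defined = FALSE` when either
#'   triangle is constant) and `n_pairs`.
#' @export
informational_connectivity <- function(rdm_a, rdm_b) {
  a <- rdm_lower_triangle(rdm_a)
  b <- rdm_lower_triangle(rdm_b)
  stopifnot(length(a) == length(b))
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant RDM triangle: informational connectivity undefined")
    return(list(rho = NA_real_, defined = FALSE, n_pairs = length(a)))
  }
  rho <- cor(a, b, method = "spearman")
  list(rho = rho, defined = TRUE, n_pairs = length(a))
}

#' Informational connectivity per condition cell
#'
#' Computes frontal-occipital connectivity for every cell of the
#' attention x target-frequency x time-on-task design (correct trials,
#' trial counts equalized across the 8 cells), and optionally the
#' correct-vs-miss contrast (attended trials only): per cell, correct
#' trials are subsampled to the miss count and connectivity is averaged
#' over `n_reps` subsamples.
#'
#' @param binned Pooled `distance_binned_set` with condition labels.
#' @param groups Named list with `frontal` and `occipital` sensor indices
#'   (see [sensor_groups()]).
#' @param outcome_contrast If `TRUE`, adds miss cells and rep-averaged
#'   correct cells over the target-frequency x time-on-task design.
#' @param n_reps Correct-trial subsampling repetitions for the
#'   correct-vs-miss comparison (default 100).
#' @param n_folds,seed,shrinkage Decoding parameters.
#' @param min_per_cell Minimum trials required per cell.
#' @return data.frame with one row per (attention, frequency, half
#'   \[, outcome\]) cell: `rho` (mean over reps), `n_reps`, `n_trials`.
#' @export
connectivity_by_condition <- function(binned, groups, outcome_contrast = FALSE,
                                      n_reps = 100L, n_folds = 10L, seed = 1L,
                                      shrinkage = "auto", min_per_cell = 12L) {
  lab <- binned$labels
  correct_mask <- !(lab$outcome %in% c("miss", "false_alarm_early",
                                       "false_alarm_event", "false_alarm_wrong_colour"))
  cell_rho <- function(trials, cell_seed, reps = 1L, sub_n = NULL) {
    rhos <- vapply(seq_len(reps), function(r) {
      tri <- trials
      if (!is.null(sub_n) && sub_n < length(trials)) {
        tri <- with_seed(derive_seed(cell_seed, "rep", r), sort(sample(trials, sub_n)))
      }
      sub <- subset_binned(binned, tri)
      ra <- group_rdm(sub, groups$frontal, n_folds, derive_seed(cell_seed, "rdm", r), shrinkage)
      rb <- group_rdm(sub, groups$occipital, n_folds, derive_seed(cell_seed, "rdm", r), shrinkage)
      informational_connectivity(ra, rb)$rho
    }, numeric(1))
    mean(rhos, na.rm = TRUE)
  }

  if (!outcome_contrast) {
    cells <- expand.grid(attention = c("attended", "unattended"),
                         frequency = c("active", "monitoring"),
                         half = c("early", "late"),
                         stringsAsFactors = FALSE)
    sets <- lapply(seq_len(nrow(cells)), function(i) {
      which(correct_mask &
              lab$attended == (cells$attention[i] == "attended") &
              lab$condition == cells$frequency[i] &
              !is.na(lab$epoch_half) & lab$epoch_half == cells$half[i])
    })
    names(sets) <- paste(cells$attention, cells$frequency, cells$half, sep = ".")
    sizes <- vapply(sets, length, integer(1))
    if (any(sizes < min_per_cell)) {
      stop("empty or too-small condition cell(s): ",
           paste(names(sets)[sizes < min_per_cell], collapse = ", "))
    }
    sets <- equalize_trial_counts(sets, derive_seed(seed, "equalize"))
    cells$rho <- vapply(seq_len(nrow(cells)), function(i) {
      cell_rho(sets[[i]], derive_seed(seed, "cell", i))
    }, numeric(1))
    cells$n_reps <- 1L
    cells$n_trials <- vapply(sets, length, integer(1))
    return(cells)
  }

  # correct-vs-miss contrast: attended only, frequency x half x outcome
  cells <- expand.grid(frequency = c("active", "monitoring"),
                       half = c("early", "late"),
                       outcome = c("correct", "miss"),
                       stringsAsFactors = FALSE)
  cells$attention <- "attended"
  res <- numeric(nrow(cells)); ntr <- integer(nrow(cells)); nrp <- integer(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    base <- lab$attended & lab$condition == cells$frequency[i] &
      !is.na(lab$epoch_half) & lab$epoch_half == cells$half[i]
    miss_tr <- which(base & lab$outcome == "miss")
    corr_tr <- which(base & correct_mask)
    if (length(miss_tr) < min_per_cell) {
      stop("correct-vs-miss contrast needs >= ", min_per_cell, " miss trials in cell ",
           cells$frequency[i], ".", cells$half[i], " (found ", length(miss_tr), ")")
    }
    if (cells$outcome[i] == "miss") {
      res[i] <- cell_rho(miss_tr, derive_seed(seed, "miss", i))
      ntr[i] <- length(miss_tr); nrp[i] <- 1L
    } else {
      res[i] <- cell_rho(corr_tr, derive_seed(seed, "corr", i),
                         reps = n_reps, sub_n = length(miss_tr))
      ntr[i] <- length(miss_tr); nrp[i] <- n_reps
    }
  }
  cells$rho <- res; cells$n_reps <- nrp; cells$n_trials <- ntr
  cells[, c("attention", "frequency", "half", "outcome", "rho", "n_reps", "n_trials")]
}
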