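#' Bin epochs into per-trial distance windows
#'
#' Divides each trial's onset-to-deflection span into `n_bins` equal time
#' windows (at constant dot speed, equal time equals equal screen distance)
#' and extracts one feature vector per window. Distance indexing follows
#' the task: bin `n_bins` (default 15) is the farthest window, just after
#' the dot appears; bin 1 is nearest the central object, ending at the
#' deflection point. A sample falling exactly on a window boundary belongs
#' to the later window, i.e. the nearer-object (lower-index) bin.
#'
#' Within each window, `samples_per_bin` samples are retained by uniform
#' decimation so every trial and bin yields a feature vector of identical
#' length (`sensors * samples_per_bin`), flattened sensor-major
#' (all retained samples of sensor 1, then sensor 2, ...).
#'
#' @param epochs An [epoch_set()] with `deflection_ms` in its labels.
#' @param n_bins Number of distance bins.
#' @param samples_per_bin Samples retained per bin.
#' @return A `distance_binned_set`: `features` array
#'   `trials x n_bins x (sensors * samples_per_bin)`, `labels`,
#'   `bin_edges_ms` (`trials x (n_bins + 1)`, onset to deflection),
#'   `sensor_ids`, `samples_per_bin`, `pooled` flag.
#' @export
bin_distances <- function(epochs, n_bins = 15L, samples_per_bin = 5L) {
  lab <- epochs$labels
  stopifnot("deflection_ms" %in% names(lab))
  n <- n_trials(epochs)
  n_sens <- dim(epochs$data)[2]
  feat_len <- n_sens * samples_per_bin
  features <- array(NA_real_, dim = c(n, n_bins, feat_len))
  edges <- matrix(NA_real_, n, n_bins + 1)

  for (i in seq_len(n)) {
    defl <- lab$deflection_ms[i]
    e <- seq(0, defl, length.out = n_bins + 1)
    edges[i, ] <- e
    for (k in seq_len(n_bins)) {        # k-th time window -> distance bin
      d_bin <- n_bins - k + 1L
      # boundary rule: [lo, hi); sample at hi belongs to the next window
      in_win <- which(epochs$time_ms >= e[k] & epochs$time_ms < e[k + 1])
      if (length(in_win) == 0) {
        stop("trial ", i, ": distance bin ", d_bin,
             " contains no samples; epoch too short or fs too low")
      }
      pick <- in_win[unique_round_seq(length(in_win), samples_per_bin)]
      seg <- epochs$data[i, , pick, drop = TRUE]
      if (n_sens == 1L) seg <- matrix(seg, nrow = 1)
      if (samples_per_bin == 1L) seg <- matrix(seg, ncol = 1)
      features[i, d_bin, ] <- as.vector(t(seg))   # sensor-major, time-minor
    }
  }
  structure(list(features = features, labels = lab, bin_edges_ms = edges,
                 n_bins = n_bins, samples_per_bin = samples_per_bin,
                 sensor_ids = seq_len(n_sens), pooled = FALSE,
                 subject_id = epochs$subject_id),
            class = "distance_binned_set")
}

# indices of `k` approximately uniformly spaced picks out of `n`
unique_round_seq <- function(n, k) {
  if (n <= k) return(rep(seq_len(n), length.out = k))
  round(seq(1, n, length.out = k))
}

#' Pool left and right directions of approach into shared distance classes
#'
#' Distance decoding is made direction-invariant by pooling trials from
#' both entry corners under the same distance labels; the direction label
#' is retained for bookkeeping only. Idempotent.
#'
#' @param binned A `distance_binned_set`.
#' @return The set marked as pooled.
#' @export
pool_directions <- function(binned) {
  stopifnot(inherits(binned, "distance_binned_set"))
  if (binned$pooled) return(binned)
  dirs <- unique(binned$labels$direction)
  if (length(dirs) < 2) {
    warning("only one direction of approach present; pooling is a no-op")
  }
  binned$pooled <- TRUE
  binned
}

#' Subset a distance-binned set by trial
#' @param binned A `distance_binned_set`.
#' @param idx Trial indices or logical mask.
#' @return Restricted set.
#' @export
subset_binned <- function(binned, idx) {
  binned$features <- binned$features[idx, , , drop = FALSE]
  binned$labels <- binned$labels[idx, , drop = FALSE]
  binned$bin_edges_ms <- binned$bin_edges_ms[idx, , drop = FALSE]
  binned
}

#' Restrict a distance-binned set to a sensor group
#' @param binned A `distance_binned_set`.
#' @param sensors Sensor indices (within the set's `sensor_ids`).
#' @return Set whose feature vectors keep only those sensors' columns.
#' @export
subset_sensors_binned <- function(binned, sensors) {
  if (length(sensors) == 0) stop("empty sensor group")
  pos <- match(sensors, binned$sensor_ids)
  if (anyNA(pos)) stop("sensor group indexes sensors not present in the set")
  spb <- binned$samples_per_bin
  cols <- as.vector(vapply(pos, function(p) ((p - 1L) * spb + 1L):(p * spb),
                           integer(spb)))
  binned$features <- binned$features[, , cols, drop = FALSE]
  binned$sensor_ids <- binned$sensor_ids[pos]
  binned
}

#' Named sensor groups
#'
#' @param n_sensors Total sensor count.
#' @param frontal,occipital Index vectors; defaults are the first and last
#'   quartile of the sensor range (the groups used by the informational
#'   connectivity analysis).
#' @return Named list of index vectors with an `all` entry.
#' @export
sensor_groups <- function(n_sensors, frontal = NULL, occipital = NULL) {
  q <- max(1L, floor(n_sensors / 4))
  if (is.null(frontal)) frontal <- seq_len(q)
  if (is.null(occipital)) occipital <- seq(n_sensors - q + 1L, n_sensors)
  groups <- list(frontal = as.integer(frontal),
                 occipital = as.integer(occipital),
                 all = seq_len(n_sensors))
  if (any(vapply(groups, length, integer(1)) == 0)) stop("sensor groups must be non-empty")
  if (any(unlist(groups) < 1 | unlist(groups) > n_sensors)) {
    stop("sensor group indices out of range")
  }
  groups
}

#' Equalize trial counts across labelled sets
#'
#' Subsamples every set, without replacement, to the global minimum size.
#'
#' @param sets Named list of integer index vectors (trial ids per condition
#'   cell).
#' @param seed Integer seed.
#' @return List of subsampled index vectors (same names).
#' @export
equalize_trial_counts <- function(sets, seed = 1L) {
  sizes <- vapply(sets, length, integer(1))
  if (any(sizes == 0)) {
    empty <- names(sets)[sizes == 0]
    if (is.null(empty)) empty <- which(sizes == 0)
    stop("cannot equalize: empty condition set(s): ", paste(empty, collapse = ", "))
  }
  m <- min(sizes)
  with_seed(seed, {
    lapply(sets, function(s) if (length(s) == m) s else sort(sample(s, m)))
  })
}
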