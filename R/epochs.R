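#' Construct an epoch set
#'
#' Container for epoched multi-sensor time series: a trials x sensors x
#' samples array, a strictly increasing uniform time axis, and a per-trial
#' label table.
#'
#' @param data Numeric array `trials x sensors x samples`.
#' @param time_ms Per-sample times in ms (uniform step `1000 / fs_hz`).
#' @param fs_hz Sampling rate.
#' @param labels data.frame with one row per trial.
#' @param subject_id Identifier carried through outputs.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(data, time_ms, fs_hz, labels, subject_id = "s1") {
  stopifnot(length(dim(data)) == 3, dim(data)[3] == length(time_ms),
            nrow(labels) == dim(data)[1])
  step <- diff(time_ms)
  if (any(step <= 0) || max(abs(step - 1000 / fs_hz)) > 1e-6) {
    stop("time axis must be strictly increasing with uniform step 1000/fs_hz")
  }
  if ("deflection_ms" %in% names(labels)) {
    if (any(labels$deflection_ms < time_ms[1] | labels$deflection_ms > time_ms[length(time_ms)])) {
      stop("deflection_ms must lie within the epoch window")
    }
  }
  structure(list(data = data, time_ms = time_ms, fs_hz = fs_hz,
                 labels = labels, subject_id = subject_id),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> subject %s: %d trials x %d sensors x %d samples @ %g Hz (%g..%g ms)\n",
              x$subject_id, d[1], d[2], d[3], x$fs_hz,
              x$time_ms[1], x$time_ms[length(x$time_ms)]))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs An `epoch_set`.
#' @return Integer trial count.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset an epoch set by trial
#' @param epochs An `epoch_set`.
#' @param idx Trial indices or logical mask.
#' @return An `epoch_set` restricted to those trials.
#' @export
subset_trials <- function(epochs, idx) {
  epoch_set(epochs$data[idx, , , drop = FALSE], epochs$time_ms, epochs$fs_hz,
            epochs$labels[idx, , drop = FALSE], epochs$subject_id)
}

#' Simulate multi-sensor epochs for a schedule
#'
#' One epoch per dot over the sensor model's epoch window. The signal is
#' `attention_gain(colour) * [a_trial * sign(direction) * direction_pattern * s(t)
#'  + distance_pattern(bin(t)) * s(t)] + noise`, where `s(t)` is a box-car
#' from 100 ms post-onset to the deflection point with 20-ms half-cosine
#' ramps, `bin(t)` is the dot's instantaneous distance bin (15 just after
#' onset down to 1 at the deflection point), and `a_trial` is per-trial
#' direction-amplitude jitter. On miss trials the distance term is
#' multiplied by `miss_attenuation` and the jitter SD by
#' `miss_direction_noise_inflation`. The frontal copy of the distance
#' patterns is scaled by the attention-dependent frontal coupling.
#'
#' @param schedule Schedule with outcomes filled.
#' @param model A [sensor_model()].
#' @param seed Integer seed.
#' @param trials Optional row indices of `schedule` to simulate (defaults to
#'   all non-practice dots).
#' @param subject_id Subject identifier.
#' @param early_blocks,late_blocks Block index sets for the time-on-task
#'   (`epoch_half`) label.
#' @return An [epoch_set()] whose labels carry `direction`, `colour`,
#'   `attended`, `condition`, `block`, `epoch_half`, `outcome`,
#'   `deflection_ms` and `dot_id`.
#' @export
simulate_epochs <- function(schedule, model = sensor_model(), seed = 1L,
                            trials = NULL, subject_id = "s1",
                            early_blocks = 1:5, late_blocks = 11:15) {
  stopifnot(inherits(model, "mom_sensor_model"))
  if (is.null(trials)) trials <- which(!schedule$is_practice)
  sch <- schedule[trials, , drop = FALSE]
  n <- nrow(sch)
  step <- 1000 / model$fs_hz
  time_ms <- seq(model$epoch_window_ms[1], model$epoch_window_ms[2], by = step)
  n_samp <- length(time_ms)
  n_sens <- model$n_sensors

  labels <- data.frame(
    dot_id = sch$dot_id,
    direction = sch$direction,
    colour = sch$colour,
    attended = sch$colour == "cued",
    condition = sch$condition,
    block = sch$block,
    epoch_half = ifelse(sch$block %in% early_blocks, "early",
                        ifelse(sch$block %in% late_blocks, "late", NA_character_)),
    outcome = sch$outcome,
    deflection_ms = pmin(sch$deflection_ms, model$epoch_window_ms[2]),
    stringsAsFactors = FALSE
  )

  data <- array(0, dim = c(n, n_sens, n_samp))
  with_seed(seed, {
    for (i in seq_len(n)) {
      defl <- labels$deflection_ms[i]
      s_t <- ramped_boxcar(time_ms, 100, defl, ramp_ms = 20)
      is_miss <- labels$outcome[i] == "miss"
      gain <- if (labels$attended[i]) model$attention_gain else 1

      amp_sd <- model$dir_amp_sd * if (is_miss) model$miss_direction_noise_inflation else 1
      a_trial <- rnorm(1, 1, amp_sd)
      dsign <- if (labels$direction[i] == "left") 1 else -1

      fc <- if (labels$attended[i]) model$frontal_coupling_attended else model$frontal_coupling_unattended
      att <- if (is_miss) model$miss_attenuation else 1

      # instantaneous distance bin: 15 equal time windows over [0, defl)
      bin_idx <- instantaneous_bin(time_ms, defl)
      dist_mat <- matrix(0, n_sens, n_samp)
      active <- which(!is.na(bin_idx) & s_t > 0)
      if (length(active)) {
        pat <- model$distance_patterns$occipital[, bin_idx[active], drop = FALSE] +
          fc * model$distance_patterns$frontal[, bin_idx[active], drop = FALSE]
        dist_mat[, active] <- pat * rep(s_t[active], each = n_sens)
      }
      dir_mat <- (a_trial * dsign * model$direction_pattern) %o% s_t
      sig <- gain * (dir_mat + att * dist_mat)
      data[i, , ] <- sig + matrix(rnorm(n_sens * n_samp, 0, model$noise_sd),
                                  n_sens, n_samp)
    }
  })
  epoch_set(data, time_ms, model$fs_hz, labels, subject_id)
}

# box-car over [start, stop] with half-cosine on/off ramps of `ramp_ms`
ramped_boxcar <- function(time_ms, start, stop, ramp_ms = 20) {
  s <- numeric(length(time_ms))
  up <- time_ms >= start & time_ms < start + ramp_ms
  s[up] <- 0.5 * (1 - cos(pi * (time_ms[up] - start) / ramp_ms))
  flat <- time_ms >= start + ramp_ms & time_ms <= stop - ramp_ms
  s[flat] <- 1
  down <- time_ms > stop - ramp_ms & time_ms <= stop
  s[down] <- 0.5 * (1 - cos(pi * (stop - time_ms[down]) / ramp_ms))
  s
}

# distance bin of each sample: bin 15 for t in [0, w), ..., bin 1 for the
# last window before deflection; NA outside [0, defl)
instantaneous_bin <- function(time_ms, deflection_ms, n_bins = 15L) {
  w <- deflection_ms / n_bins
  k <- floor(time_ms / w)            # time-order window 0..14
  bin <- n_bins - k                  # distance index 15..1
  bin[time_ms < 0 | time_ms >= deflection_ms] <- NA_integer_
  as.integer(bin)
}

#' Downsample an epoch set
#'
#' FIR anti-alias low-pass (windowed-sinc, cutoff at 80% of the new Nyquist)
#' followed by decimation. The factor must be an integer; the first sample
#' (epoch start) is always retained, so a window of -100..3000 ms at
#' 1000 Hz becomes 621 samples at 200 Hz.
#'
#' @param epochs An [epoch_set()].
#' @param target_fs Target sampling rate; must divide `fs_hz`.
#' @return A downsampled `epoch_set` with the time axis re-derived and the
#'   labels unchanged.
#' @export
downsample <- function(epochs, target_fs) {
  r <- epochs$fs_hz / target_fs
  if (abs(r - round(r)) > 1e-9) stop("target_fs must divide fs_hz (integer decimation)")
  r <- as.integer(round(r))
  if (r == 1L) return(epochs)

  ntaps <- 65L
  h <- signal::fir1(ntaps - 1L, 0.8 / r)
  h <- h / sum(h)                                    # exact unit DC gain
  half <- (ntaps - 1L) %/% 2L
  d <- dim(epochs$data)
  keep <- seq(1L, d[3], by = r)
  out <- array(0, dim = c(d[1], d[2], length(keep)))
  for (i in seq_len(d[1])) {
    x <- t(epochs$data[i, , , drop = TRUE])            # samples x sensors
    if (d[2] == 1L) x <- matrix(epochs$data[i, 1, ], ncol = 1)
    # reflect-pad edges so the symmetric FIR has full support everywhere
    xp <- rbind(x[(half + 1):2, , drop = FALSE], x,
                x[(nrow(x) - 1):(nrow(x) - half), , drop = FALSE])
    y <- stats::filter(xp, h, sides = 2)
    y <- y[(half + 1):(half + nrow(x)), , drop = FALSE]
    out[i, , ] <- t(y[keep, , drop = FALSE])
  }
  epoch_set(out, epochs$time_ms[keep], target_fs, epochs$labels, epochs$subject_id)
}

#' Convenience: simulate one subject end to end
#'
#' Schedule, behaviour and epochs for a single synthetic subject, with
#' stage seeds derived from a master seed.
#'
#' @param master_seed Master integer seed.
#' @param subject_id Subject identifier (also enters seed derivation).
#' @param config,behaviour,sensors Component models.
#' @param trials Optional schedule rows to simulate epochs for.
#' @param early_blocks,late_blocks Passed to [simulate_epochs()].
#' @return List with `schedule` (outcomes filled) and `epochs`.
#' @export
simulate_subject <- function(master_seed, subject_id = "s1",
                             config = task_config(),
                             behaviour = behaviour_model(),
                             sensors = sensor_model(),
                             trials = NULL,
                             early_blocks = 1:5, late_blocks = 11:15) {
  sch <- generate_schedule(config, derive_seed(master_seed, subject_id, "schedule"))
  sch <- simulate_behaviour(sch, behaviour, derive_seed(master_seed, subject_id, "behaviour"))
  ep <- simulate_epochs(sch, sensors, derive_seed(master_seed, subject_id, "epochs"),
                        trials = trials, subject_id = subject_id,
                        early_blocks = early_blocks, late_blocks = late_blocks)
  list(schedule = sch, epochs = ep)
}
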