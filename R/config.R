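#' Task configuration for the multiple-object monitoring (MOM) paradigm
#'
#' Describes the block structure and trial timing of the MOM task: dots move
#' from a screen corner towards a central object and normally deflect away at
#' a fixed deflection point; target dots fail to deflect and must be
#' intercepted by a button press before they collide with the object. Blocks
#' come in two target-frequency conditions: \emph{Active} (half the
#' cued-colour dots are targets) and \emph{Monitoring} (targets are rare,
#' about 6\% of cued dots), run as two sets of consecutive blocks.
#'
#' @param block_duration_s Block length in seconds.
#' @param dots_per_block Number of dots per block (both colours).
#' @param dots_per_colour Dots of each colour per block; twice this must equal
#'   `dots_per_block`.
#' @param targets_active,targets_monitoring Number of cued-colour target dots
#'   per Active / Monitoring block. The same number of non-cued dots per block
#'   fail to deflect (distractor events).
#' @param n_blocks_per_condition Main-experiment blocks per condition.
#' @param practice_blocks Practice blocks (Active condition) preceding the
#'   main experiment; flagged and excluded from analysis.
#' @param onset_to_deflection_ms,deflection_to_collision_ms,total_motion_ms,isi_ms
#'   Two-element numeric vectors `c(mean, sd)` in milliseconds. ISI is the
#'   delay between onsets of consecutive dots.
#' @param condition_order `"active_first"` or `"monitoring_first"`.
#' @param min_isi_ms Lower truncation bound for ISI draws.
#' @return A `mom_task_config` list.
#' @export
task_config <- function(block_duration_s = 110,
                        dots_per_block = 64,
                        dots_per_colour = 32,
                        targets_active = 16,
                        targets_monitoring = 2,
                        n_blocks_per_condition = 15,
                        practice_blocks = 2,
                        onset_to_deflection_ms = c(1226, 10),
                        deflection_to_collision_ms = c(410, 10),
                        total_motion_ms = c(2005, 12),
                        isi_ms = c(1660, 890),
                        condition_order = c("active_first", "monitoring_first"),
                        min_isi_ms = 100) {
  condition_order <- match.arg(condition_order)
  cfg <- list(
    block_duration_s = block_duration_s,
    dots_per_block = dots_per_block,
    dots_per_colour = dots_per_colour,
    targets_active = targets_active,
    targets_monitoring = targets_monitoring,
    n_blocks_per_condition = n_blocks_per_condition,
    practice_blocks = practice_blocks,
    onset_to_deflection_ms = onset_to_deflection_ms,
    deflection_to_collision_ms = deflection_to_collision_ms,
    total_motion_ms = total_motion_ms,
    isi_ms = isi_ms,
    condition_order = condition_order,
    min_isi_ms = min_isi_ms
  )
  class(cfg) <- "mom_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "mom_task_config"))
  if (cfg$dots_per_colour * 2L != cfg$dots_per_block) {
    stop("dots_per_colour * 2 must equal dots_per_block")
  }
  if (!(cfg$targets_monitoring <= cfg$targets_active &&
        cfg$targets_active <= cfg$dots_per_colour)) {
    stop("need targets_monitoring <= targets_active <= dots_per_colour")
  }
  if (cfg$targets_monitoring < 0) stop("target counts must be non-negative")
  durs <- c(cfg$block_duration_s,
            cfg$onset_to_deflection_ms[1], cfg$deflection_to_collision_ms[1],
            cfg$total_motion_ms[1], cfg$isi_ms[1], cfg$min_isi_ms)
  if (any(durs <= 0)) stop("all durations must be positive")
  invisible(cfg)
}

#' Behavioural outcome model
#'
#' Parametrises the probability that a target is missed as a function of
#' block number and target-frequency condition, emulating a vigilance
#' decrement: under Monitoring (rare targets) the miss probability rises
#' with time on task, while under Active (frequent targets) it falls over
#' the first blocks and then plateaus. Correct-response reaction times are
#' drawn from a truncated normal with a signed per-block trend (slower over
#' time under Monitoring, faster under Active).
#'
#' Defaults are calibrated to the characteristic block-wise pattern of the
#' task: first-block miss rates near 29\% (Active) / 40\% (Monitoring), an
#' Active plateau near 17\%, and a Monitoring rise of ~2.6 percentage points
#' per block.
#'
#' @param base_miss_prob Miss probability in block 1 (both conditions; the
#'   condition-specific offset is carried by the slopes from block 1 on).
#' @param vigilance_slope Per-block increment of the miss probability,
#'   applied in the Monitoring condition only.
#' @param active_learning_slope Per-block decrement in the Active condition.
#' @param active_plateau Floor of the Active miss probability.
#' @param rt_mean_ms,rt_sd_ms Reaction-time distribution (ms from the
#'   deflection point), truncated to (0, deflection-to-collision window].
#' @param rt_trend_ms_per_block Signed RT slope: added per block under
#'   Monitoring, subtracted under Active.
#' @param fa_rate False-alarm probability per non-target dot, split across
#'   early, auto-deflection ("event") and wrong-colour presses.
#' @param base_miss_active Optional separate block-1 miss probability for the
#'   Active condition (defaults to `base_miss_prob` minus 0.11, matching the
#'   calibrated first-block gap).
#' @return A `mom_behaviour_model` list.
#' @export
behaviour_model <- function(base_miss_prob = 0.40,
                            vigilance_slope = 0.026,
                            active_learning_slope = 0.03,
                            active_plateau = 0.17,
                            rt_mean_ms = 250,
                            rt_sd_ms = 50,
                            rt_trend_ms_per_block = 3,
                            fa_rate = 0.035,
                            base_miss_active = base_miss_prob - 0.11) {
  probs <- c(base_miss_prob, fa_rate, active_plateau, base_miss_active)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (rt_sd_ms < 0 || rt_mean_ms <= 0) stop("invalid RT parameters")
  m <- list(
    base_miss_prob = base_miss_prob,
    base_miss_active = base_miss_active,
    vigilance_slope = vigilance_slope,
    active_learning_slope = active_learning_slope,
    active_plateau = active_plateau,
    rt_mean_ms = rt_mean_ms,
    rt_sd_ms = rt_sd_ms,
    rt_trend_ms_per_block = rt_trend_ms_per_block,
    fa_rate = fa_rate
  )
  class(m) <- "mom_behaviour_model"
  m
}

#' Miss probability implied by a behaviour model
#'
#' @param model A [behaviour_model()].
#' @param block Block index within the condition (1-based).
#' @param condition `"active"` or `"monitoring"`.
#' @return Miss probability, clipped to \[0, 1\].
#' @export
miss_probability <- function(model, block, condition) {
  condition <- match.arg(condition, c("active", "monitoring"), several.ok = FALSE)
  p <- if (condition == "monitoring") {
    model$base_miss_prob + model$vigilance_slope * (block - 1)
  } else {
    pmax(model$active_plateau,
         model$base_miss_active - model$active_learning_slope * (block - 1))
  }
  pmin(pmax(p, 0), 1)
}

#' Sensor-space signal model for synthetic epochs
#'
#' Describes how task variables are written into a multi-sensor epoch.
#' The direction of approach (left vs right corner) drives a fixed smooth
#' sensor pattern with opposite sign for the two directions; the dot's
#' instantaneous distance bin (15 = just appeared, 1 = nearest the object)
#' drives one of 15 spatially ordered Gaussian-bump patterns centred on the
#' posterior ("occipital") sensor group, with a mirrored copy on the
#' anterior ("frontal") group whose amplitude depends on attention. Cued
#' (attended) trials are amplified by `attention_gain`; on miss trials the
#' distance signal is attenuated by `miss_attenuation` and the
#' trial-to-trial variability of the direction amplitude is inflated.
#'
#' Default amplitudes and noise are calibrated so that single-trial mean
#' distance-decoding accuracies centre near 0.60 for correct trials and
#' 0.56 for miss trials at the default cohort size.
#'
#' @param n_sensors Number of sensors.
#' @param fs_hz Sampling rate of generated epochs (Hz).
#' @param frontal_group,occipital_group Disjoint sensor index vectors;
#'   defaults are the first and last quartile of the sensor range.
#' @param attention_gain Multiplier (>= 0) applied to cued-colour trials.
#' @param miss_attenuation Multiplier in \[0, 1\] on the distance signal of
#'   miss trials.
#' @param miss_direction_noise_inflation Multiplier (>= 1) on the SD of the
#'   per-trial direction-amplitude jitter for miss trials.
#' @param noise_sd Per-sensor, per-sample Gaussian noise SD.
#' @param dir_strength,dist_strength Pattern amplitudes.
#' @param dir_amp_sd Baseline SD of the per-trial direction amplitude.
#' @param frontal_coupling_attended,frontal_coupling_unattended Amplitude of
#'   the frontal copy of the distance patterns on attended / unattended
#'   trials, as a fraction of the occipital amplitude.
#' @param epoch_window_ms Epoch window `c(start, end)` relative to dot onset.
#' @return A `mom_sensor_model` list (with the derived `direction_pattern`
#'   and `distance_patterns` matrices attached).
#' @export
sensor_model <- function(n_sensors = 160,
                         fs_hz = 1000,
                         frontal_group = NULL,
                         occipital_group = NULL,
                         attention_gain = 1.5,
                         miss_attenuation = 0.45,
                         miss_direction_noise_inflation = 3,
                         noise_sd = 10,
                         dir_strength = 1,
                         dist_strength = 1,
                         dir_amp_sd = 0.25,
                         frontal_coupling_attended = 1,
                         frontal_coupling_unattended = 0.3,
                         epoch_window_ms = c(-100, 3000)) {
  if (is.null(frontal_group)) frontal_group <- seq_len(max(1L, floor(n_sensors / 4)))
  if (is.null(occipital_group)) {
    occipital_group <- seq(n_sensors - max(1L, floor(n_sensors / 4)) + 1L, n_sensors)
  }
  if (length(intersect(frontal_group, occipital_group)) > 0) {
    stop("frontal and occipital groups must be disjoint")
  }
  if (any(c(frontal_group, occipital_group) < 1) ||
      any(c(frontal_group, occipital_group) > n_sensors)) {
    stop("sensor groups must index sensors within 1..n_sensors")
  }
  if (attention_gain < 0 || noise_sd < 0) stop("attention_gain and noise_sd must be >= 0")
  if (miss_attenuation < 0 || miss_attenuation > 1) stop("miss_attenuation must be in [0, 1]")
  if (miss_direction_noise_inflation < 1) stop("miss_direction_noise_inflation must be >= 1")

  m <- list(
    n_sensors = n_sensors, fs_hz = fs_hz,
    frontal_group = as.integer(frontal_group),
    occipital_group = as.integer(occipital_group),
    attention_gain = attention_gain,
    miss_attenuation = miss_attenuation,
    miss_direction_noise_inflation = miss_direction_noise_inflation,
    noise_sd = noise_sd,
    dir_strength = dir_strength, dist_strength = dist_strength,
    dir_amp_sd = dir_amp_sd,
    frontal_coupling_attended = frontal_coupling_attended,
    frontal_coupling_unattended = frontal_coupling_unattended,
    epoch_window_ms = epoch_window_ms
  )
  m$direction_pattern <- default_direction_pattern(n_sensors, dir_strength)
  m$distance_patterns <- default_distance_patterns(m)
  class(m) <- "mom_sensor_model"
  m
}

# Smooth fixed sensor topography for left/right direction: a low-order
# sinusoid across the sensor index range (deterministic, no RNG).
default_direction_pattern <- function(n_sensors, strength) {
  s <- seq_len(n_sensors)
  strength * sin(2 * pi * 3 * s / n_sensors)
}

# 15 spatially ordered Gaussian bumps: centre drifts across the occipital
# group from its far end (distance 15) to its near end (distance 1), with a
# mirrored frontal copy (scaled later by the attention-dependent coupling).
# Column d of each matrix is the pattern for distance bin d.
default_distance_patterns <- function(m) {
  n_bins <- 15L
  occ <- m$occipital_group
  fro <- m$frontal_group
  occ_centres <- seq(occ[length(occ)], occ[1], length.out = n_bins)
  fro_centres <- seq(fro[1], fro[length(fro)], length.out = n_bins)
  width <- max(1, length(occ) / 5)
  s <- seq_len(m$n_sensors)
  occ_pat <- sapply(occ_centres, function(c0) {
    p <- exp(-(s - c0)^2 / (2 * width^2))
    p[-occ] <- 0
    p
  })
  fro_pat <- sapply(fro_centres, function(c0) {
    p <- exp(-(s - c0)^2 / (2 * width^2))
    p[-fro] <- 0
    p
  })
  list(occipital = m$dist_strength * occ_pat,
       frontal   = m$dist_strength * fro_pat)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash of `(master_seed, labels...)`, kept below
#' 2^31 so it is a valid R seed. Used to fan one master seed out to
#' independent per-stage / per-subject RNG streams.
#'
#' @param master_seed Integer master seed.
#' @param ... Stage / subject labels (coerced to character).
#' @return A single integer seed.
#' @export
derive_seed <- function(master_seed, ...) {
  labels <- paste(c(master_seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a local, restored RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
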