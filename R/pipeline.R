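#' Pipeline run configuration
#'
#' Bundles every knob of an end-to-end run: the task, behaviour and sensor
#' models, cohort size, analysis parameters, stage toggles and the output
#' directory. All stage and subject seeds are derived from `master_seed`
#' with [derive_seed()], so identical configurations reproduce identical
#' outputs byte for byte.
#'
#' @param master_seed Integer master seed.
#' @param n_subjects Cohort size (default 21).
#' @param task,behaviour,sensors Component models.
#' @param stages Character vector of stages to run, a subset of
#'   `c("behaviour", "direction", "distance", "connectivity", "error",
#'   "prediction", "stats")`.
#' @param out_dir Output directory (created if needed).
#' @param samples_per_bin,n_folds,shrinkage,m_grid Analysis parameters.
#' @param epoch_trials_per_cell Epochs are simulated for at most this many
#'   trials per attention x frequency x half cell (seeded subsample;
#'   `Inf` keeps every dot). Keeps desk-scale runs tractable.
#' @param connectivity_reps Correct-trial subsampling repetitions for the
#'   connectivity outcome contrast.
#' @param direction_step_ms Time step of the direction decoder.
#' @return A `mom_run_config` list.
#' @export
run_config <- function(master_seed = 1L, n_subjects = 21L,
                       task = task_config(),
                       behaviour = behaviour_model(),
                       sensors = sensor_model(),
                       stages = c("behaviour", "direction", "distance",
                                  "connectivity", "error", "prediction", "stats"),
                       out_dir = "results",
                       samples_per_bin = 5L, n_folds = 10L,
                       shrinkage = "auto",
                       m_grid = seq(0.1, 4, by = 0.1),
                       epoch_trials_per_cell = 20L,
                       connectivity_reps = 10L,
                       direction_step_ms = 5) {
  known <- c("behaviour", "direction", "distance", "connectivity",
             "error", "prediction", "stats")
  stages <- match.arg(stages, known, several.ok = TRUE)
  structure(list(master_seed = as.integer(master_seed), n_subjects = n_subjects,
                 task = task, behaviour = behaviour, sensors = sensors,
                 stages = stages, out_dir = out_dir,
                 samples_per_bin = samples_per_bin, n_folds = n_folds,
                 shrinkage = shrinkage, m_grid = m_grid,
                 epoch_trials_per_cell = epoch_trials_per_cell,
                 connectivity_reps = connectivity_reps,
                 direction_step_ms = direction_step_ms),
            class = "mom_run_config")
}

#' Run the analysis pipeline end to end
#'
#' Executes the enabled stages in dependency order for a synthetic cohort
#' and writes one CSV per stage plus a JSON manifest (config snapshot,
#' package version, per-output MD5 hash, wall-clock per stage) to
#' `config$out_dir`. A failing stage aborts with the stage named; outputs
#' written before the failure are flagged `partial` in the manifest.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "mom_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config_snapshot(config),
                   package_version = as.character(utils::packageVersion("momdecode")),
                   stages = list())
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))

  # simulation products shared across stages
  schedules <- lapply(subjects, function(sid) {
    sch <- generate_schedule(config$task, derive_seed(config$master_seed, sid, "schedule"))
    simulate_behaviour(sch, config$behaviour, derive_seed(config$master_seed, sid, "behaviour"))
  })
  names(schedules) <- subjects
  summaries <- lapply(schedules, summarize_behaviour)

  needs_epochs <- any(config$stages %in% c("direction", "distance", "connectivity",
                                           "error", "prediction"))
  binned <- NULL; epochs_list <- NULL
  if (needs_epochs) {
    epochs_list <- lapply(subjects, function(sid) {
      sch <- schedules[[sid]]
      trials <- select_analysis_trials(sch, config$epoch_trials_per_cell,
                                       derive_seed(config$master_seed, sid, "select"))
      halves <- default_halves(config$task$n_blocks_per_condition)
      ep <- simulate_epochs(sch, config$sensors,
                            derive_seed(config$master_seed, sid, "epochs"),
                            trials = trials, subject_id = sid,
                            early_blocks = halves$early,
                            late_blocks = halves$late)
      if (ep$fs_hz > 200) ep <- downsample(ep, 200)
      ep
    })
    names(epochs_list) <- subjects
    binned <- lapply(epochs_list, function(ep) {
      pool_directions(bin_distances(ep, samples_per_bin = config$samples_per_bin))
    })
  }

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return()
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      write_manifest(manifest, config$out_dir, partial = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", elapsed_s = round(proc.time()[["elapsed"]] - t0, 2),
      outputs = file_hashes(files))
  }

  run_stage("behaviour", function() {
    tab <- do.call(rbind, lapply(subjects, function(sid) {
      cbind(subject = sid, summaries[[sid]])
    }))
    write_output(tab, config$out_dir, "behaviour_summary.csv")
  })

  run_stage("direction", function() {
    tab <- do.call(rbind, lapply(subjects, function(sid) {
      res <- decode_direction_timecourse(epochs_list[[sid]], config$n_folds,
                                         derive_seed(config$master_seed, sid, "dir"),
                                         time_step_ms = config$direction_step_ms,
                                         shrinkage = config$shrinkage)
      data.frame(subject = sid, time_ms = res$time_ms, accuracy = res$accuracy)
    }))
    write_output(tab, config$out_dir, "direction_decoding.csv")
  })

  run_stage("distance", function() {
    tab <- do.call(rbind, lapply(subjects, function(sid) {
      cells <- condition_cells(binned[[sid]]$labels)
      do.call(rbind, lapply(names(cells), function(cn) {
        sub <- subset_binned(binned[[sid]], cells[[cn]])
        rdm <- decode_distance_pairwise(sub, config$n_folds,
                                        derive_seed(config$master_seed, sid, "dist", cn),
                                        config$shrinkage)
        data.frame(subject = sid, cell = cn, distance = seq_len(rdm$n_bins),
                   accuracy = per_distance_accuracy(rdm))
      }))
    }))
    write_output(tab, config$out_dir, "distance_decoding.csv")
  })

  run_stage("connectivity", function() {
    groups <- sensor_groups(config$sensors$n_sensors,
                            config$sensors$frontal_group,
                            config$sensors$occipital_group)
    tab <- do.call(rbind, lapply(subjects, function(sid) {
      ct <- connectivity_by_condition(binned[[sid]], groups,
                                      n_folds = config$n_folds,
                                      seed = derive_seed(config$master_seed, sid, "conn"),
                                      shrinkage = config$shrinkage)
      cbind(subject = sid, ct)
    }))
    write_output(tab, config$out_dir, "connectivity.csv")
  })

  run_stage("error", function() {
    tab <- do.call(rbind, lapply(subjects, function(sid) {
      gen <- train_correct_test_miss(binned[[sid]],
                                     derive_seed(config$master_seed, sid, "err"),
                                     config$shrinkage)
      dist <- single_trial_accuracy_distributions(gen)
      data.frame(subject = sid, mean_correct = dist$mean_correct,
                 mean_miss = dist$mean_miss, cohens_d = dist$cohens_d,
                 n_miss = length(gen$miss_trials), n_folds = gen$n_folds)
    }))
    write_output(tab, config$out_dir, "error_distributions.csv")
  })

  run_stage("prediction", function() {
    preps <- lapply(subjects, function(sid) {
      prepare_prediction_subject(binned[[sid]],
                                 derive_seed(config$master_seed, sid, "pred"),
                                 config$shrinkage)
    })
    loso <- loso_predict(preps, config$m_grid)
    tab <- do.call(rbind, lapply(seq_along(subjects), function(s) {
      data.frame(subject = subjects[s], distance = seq_len(ncol(loso$accuracy)),
                 accuracy = loso$accuracy[s, ], best_m = loso$best_m[s],
                 transfer_m = loso$transfer_m[s])
    }))
    f1 <- write_output(tab, config$out_dir, "prediction_accuracy.csv")
    f2 <- file.path(config$out_dir, "prediction_summary.json")
    jsonlite::write_json(list(best_m = loso$best_m, transfer_m = loso$transfer_m,
                              mean_accuracy_by_distance = colMeans(loso$accuracy)),
                         f2, digits = NA, auto_unbox = TRUE)
    c(f1, f2)
  })

  run_stage("stats", function() {
    halves <- default_halves(config$task$n_blocks_per_condition)
    bw <- blockwise_condition_bf(summaries, "miss_rate")
    interaction <- behaviour_interaction_bf(summaries, halves$early, halves$late)
    tab <- rbind(
      data.frame(effect = "miss_rate_monitoring_vs_active", location = paste0("block", bw$block),
                 bf10 = bw$bf10, category = bw$category),
      data.frame(effect = "miss_rate_vigilance_interaction", location = "overall",
                 bf10 = interaction$bf10, category = interaction$category))
    write_output(tab, config$out_dir, "bf_tables.csv")
  })

  manifest <- write_manifest(manifest, config$out_dir, partial = FALSE)
  invisible(manifest)
}

# cells of the attention x frequency x half design (correct trials)
condition_cells <- function(lab) {
  ok <- lab$outcome %in% c("hit", "correct_reject", "none")
  cells <- expand.grid(att = c(TRUE, FALSE), freq = c("active", "monitoring"),
                       half = c("early", "late"), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    which(ok & lab$attended == cells$att[i] & lab$condition == cells$freq[i] &
            !is.na(lab$epoch_half) & lab$epoch_half == cells$half[i])
  })
  names(out) <- paste(ifelse(cells$att, "attended", "unattended"),
                      cells$freq, cells$half, sep = ".")
  out[vapply(out, length, integer(1)) > 0]
}

# seeded per-cell subsample of analysis trials (keeps all miss/false-alarm
# trials, which downstream stages need in full)
select_analysis_trials <- function(schedule, per_cell, seed) {
  main <- which(!schedule$is_practice)
  if (!is.finite(per_cell)) return(main)
  lab <- schedule[main, ]
  halves <- default_halves(max(lab$block))
  half <- ifelse(lab$block %in% halves$early, "early",
                 ifelse(lab$block %in% halves$late, "late", "mid"))
  cell <- paste(lab$colour, lab$condition, half)
  keep_err <- lab$outcome %in% c("miss", "false_alarm_early", "false_alarm_event",
                                 "false_alarm_wrong_colour")
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_along(main), cell), function(ix) {
      ok <- ix[!keep_err[ix]]
      if (length(ok) > per_cell) ok <- sort(sample(ok, per_cell))
      c(ix[keep_err[ix]], ok)
    }))
    sort(main[keep])
  })
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$task <- unclass(snap$task)
  snap$behaviour <- unclass(snap$behaviour)
  sens <- unclass(snap$sensors)
  sens$direction_pattern <- NULL; sens$distance_patterns <- NULL
  snap$sensors <- sens
  snap
}

write_output <- function(df, dir, name) {
  f <- file.path(dir, name)
  utils::write.csv(df, f, row.names = FALSE)
  f
}

file_hashes <- function(files) {
  lapply(files, function(f) list(file = basename(f),
                                 md5 = unname(tools::md5sum(f))))
}

write_manifest <- function(manifest, out_dir, partial) {
  manifest$partial <- partial
  manifest$written_at <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}

#' Write an epoch set to a directory container
#'
#' Layout: `meta.json` (sampling rate, window, dimensions, subject id),
#' `labels.csv` (per-trial label table) and `data.rds` (the trials x
#' sensors x samples array).
#'
#' @param epochs An [epoch_set()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epoch_dir <- function(epochs, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(subject_id = epochs$subject_id, fs_hz = epochs$fs_hz,
                            n_trials = dim(epochs$data)[1],
                            n_sensors = dim(epochs$data)[2],
                            n_samples = dim(epochs$data)[3],
                            time_start_ms = epochs$time_ms[1],
                            time_end_ms = epochs$time_ms[length(epochs$time_ms)]),
                       file.path(path, "meta.json"), digits = NA, auto_unbox = TRUE)
  utils::write.csv(epochs$labels, file.path(path, "labels.csv"), row.names = FALSE)
  saveRDS(epochs$data, file.path(path, "data.rds"))
  invisible(path)
}

#' Load an epoch set from a directory container
#'
#' Schema-tolerant reader for the layout of [write_epoch_dir()]: missing
#' files or metadata keys raise an explicit schema error listing what was
#' found. The loaded set is re-validated through [epoch_set()].
#'
#' @param path Container directory.
#' @return An [epoch_set()].
#' @export
read_epoch_dir <- function(path) {
  found <- list.files(path)
  need <- c("meta.json", "labels.csv", "data.rds")
  if (!all(need %in% found)) {
    stop("epoch container schema error at ", path, ": expected ",
         paste(need, collapse = ", "), "; found ",
         if (length(found)) paste(found, collapse = ", ") else "nothing")
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  need_keys <- c("subject_id", "fs_hz", "n_trials", "n_sensors", "n_samples",
                 "time_start_ms")
  missing <- setdiff(need_keys, names(meta))
  if (length(missing)) {
    stop("epoch container schema error: missing metadata keys ",
         paste(missing, collapse = ", "), "; found keys ",
         paste(names(meta), collapse = ", "))
  }
  data <- readRDS(file.path(path, "data.rds"))
  labels <- utils::read.csv(file.path(path, "labels.csv"), stringsAsFactors = FALSE)
  time_ms <- meta$time_start_ms + (seq_len(meta$n_samples) - 1) * 1000 / meta$fs_hz
  epoch_set(data, time_ms, meta$fs_hz, labels, meta$subject_id)
}
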