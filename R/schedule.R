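#' Generate a MOM task schedule
#'
#' Lays out every dot of the experiment: per block, `dots_per_block` dots
#' (half per colour), with the condition-specific number of cued-colour
#' targets and the same number of non-cued distractor events; onsets drawn
#' from the truncated-normal ISI distribution and rescaled linearly when
#' needed so every dot starts within its block; per-dot timing landmarks
#' (deflection, collision) drawn from their configured mean +/- sd.
#' Directions of approach (left / right entry corner) are balanced within
#' each block and colour.
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the schedule is a deterministic function of
#'   `(config, seed)`.
#' @return A data.frame with one row per dot: `dot_id`, `condition`
#'   (`"active"`/`"monitoring"`), `block` (index within condition),
#'   `is_practice`, `onset_ms` (from block start), `colour`
#'   (`"cued"`/`"noncued"`), `direction` (`"left"`/`"right"`), `role`
#'   (`"target"`, `"event"`, `"distractor_event"`), `deflection_ms`,
#'   `collision_ms` (from dot onset), `outcome` (`"none"` until
#'   [simulate_behaviour()]), `rt_ms` (NA).
#' @export
generate_schedule <- function(config, seed = 1L) {
  validate_task_config(config)
  block_ms <- config$block_duration_s * 1000
  if (config$dots_per_block * config$min_isi_ms > block_ms) {
    stop("scheduling error: ", config$dots_per_block,
         " dots cannot fit a ", block_ms, " ms block at the minimum ISI of ",
         config$min_isi_ms, " ms")
  }

  conds <- if (config$condition_order == "active_first") {
    c("active", "monitoring")
  } else c("monitoring", "active")
  blocks <- data.frame(
    condition = c(rep(conds[1], config$practice_blocks),
                  rep(conds, each = config$n_blocks_per_condition)),
    block = c(seq_len(config$practice_blocks),
              rep(seq_len(config$n_blocks_per_condition), 2)),
    is_practice = c(rep(TRUE, config$practice_blocks),
                    rep(FALSE, 2 * config$n_blocks_per_condition))
  )
  # practice blocks use the Active condition regardless of order
  blocks$condition[blocks$is_practice] <- "active"

  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
      generate_block(config, blocks$condition[i], blocks$block[i],
                     blocks$is_practice[i])
    }))
    out$dot_id <- seq_len(nrow(out))
    out
  })
}

generate_block <- function(config, condition, block, is_practice) {
  n <- config$dots_per_block
  npc <- config$dots_per_colour
  n_targets <- if (condition == "active") config$targets_active else config$targets_monitoring
  block_ms <- config$block_duration_s * 1000

  colour <- sample(rep(c("cued", "noncued"), each = npc))
  role <- rep("event", n)
  role[sample(which(colour == "cued"), n_targets)] <- "target"
  role[sample(which(colour == "noncued"), n_targets)] <- "distractor_event"

  # balanced directions within colour, then shuffled across the block order
  direction <- character(n)
  for (cl in c("cued", "noncued")) {
    idx <- which(colour == cl)
    direction[idx] <- sample(rep(c("left", "right"), length.out = length(idx)))
  }

  isi <- rnorm(n - 1, config$isi_ms[1], config$isi_ms[2])
  isi <- pmax(isi, config$min_isi_ms)
  onset <- cumsum(c(runif(1, 0, config$min_isi_ms), isi))
  if (max(onset) > block_ms - 1) {
    onset <- onset * (block_ms - 1) / max(onset)
  }

  deflection <- rnorm(n, config$onset_to_deflection_ms[1], config$onset_to_deflection_ms[2])
  collision <- deflection +
    rnorm(n, config$deflection_to_collision_ms[1], config$deflection_to_collision_ms[2])

  data.frame(
    dot_id = NA_integer_,
    condition = condition, block = block, is_practice = is_practice,
    onset_ms = onset, colour = colour, direction = direction, role = role,
    deflection_ms = deflection, collision_ms = collision,
    outcome = "none", rt_ms = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Simulate behavioural outcomes for a schedule
#'
#' Fills per-dot outcomes and reaction times. Each cued target is missed
#' with the block- and condition-dependent probability of the behaviour
#' model (see [miss_probability()]); hits receive an RT drawn from a normal
#' distribution truncated to the deflection-to-collision window, with the
#' model's signed per-block trend. Non-target dots generate false alarms at
#' `fa_rate`, split across the three press types: early presses and presses
#' on auto-deflecting cued events, and presses on wrong-colour dots.
#' Presses are generated per dot, so press-to-dot attribution is exact by
#' construction. Cued events without a press are correct rejections.
#'
#' @param schedule Output of [generate_schedule()].
#' @param model A [behaviour_model()].
#' @param seed Integer seed.
#' @return The schedule with `outcome` and `rt_ms` filled.
#' @export
simulate_behaviour <- function(schedule, model = behaviour_model(), seed = 1L) {
  stopifnot(is.data.frame(schedule), inherits(model, "mom_behaviour_model"))
  with_seed(seed, {
    n <- nrow(schedule)
    out <- schedule
    is_target <- out$role == "target" & out$colour == "cued"

    p_miss <- miss_probability_vec(model, out$block, out$condition)
    miss <- is_target & runif(n) < p_miss
    out$outcome[is_target] <- ifelse(miss[is_target], "miss", "hit")

    hits <- which(out$outcome == "hit")
    if (length(hits)) {
      trend <- ifelse(out$condition[hits] == "monitoring", 1, -1) *
        model$rt_trend_ms_per_block * (out$block[hits] - 1)
      upper <- out$collision_ms[hits] - out$deflection_ms[hits]
      out$rt_ms[hits] <- rtruncnorm(length(hits), model$rt_mean_ms + trend,
                                    model$rt_sd_ms, lower = 0, upper = upper)
    }

    nontarget <- which(!is_target)
    fa <- nontarget[runif(length(nontarget)) < model$fa_rate]
    if (length(fa)) {
      cued_fa <- fa[out$colour[fa] == "cued"]
      wrong_fa <- fa[out$colour[fa] == "noncued"]
      out$outcome[wrong_fa] <- "false_alarm_wrong_colour"
      if (length(cued_fa)) {
        early <- runif(length(cued_fa)) < 0.5
        out$outcome[cued_fa] <- ifelse(early, "false_alarm_early", "false_alarm_event")
      }
      # a press happened: give it an attributed RT (from the deflection point)
      out$rt_ms[fa] <- rtruncnorm(length(fa), model$rt_mean_ms, model$rt_sd_ms,
                                  lower = -out$deflection_ms[fa],
                                  upper = out$collision_ms[fa] - out$deflection_ms[fa])
    }
    cr <- out$colour == "cued" & out$role != "target" & out$outcome == "none"
    out$outcome[cr] <- "correct_reject"
    out
  })
}

miss_probability_vec <- function(model, block, condition) {
  p <- ifelse(condition == "monitoring",
              model$base_miss_prob + model$vigilance_slope * (block - 1),
              pmax(model$active_plateau,
                   model$base_miss_active - model$active_learning_slope * (block - 1)))
  pmin(pmax(p, 0), 1)
}

# Truncated normal by inverse-CDF (vectorised over mean/upper).
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- pnorm(lower, mean, sd)
  pu <- pnorm(upper, mean, sd)
  qnorm(pl + runif(n) * (pu - pl), mean, sd)
}

#' Per-block behavioural summary
#'
#' @param schedule Schedule with outcomes filled (see [simulate_behaviour()]).
#' @param include_practice Include practice blocks? Default `FALSE`.
#' @return A data.frame with one row per (condition, block): `miss_rate`
#'   (misses / targets; `NA` with `undefined = TRUE` for blocks without
#'   targets, never coerced to zero), `mean_correct_rt_ms` (hits only) and
#'   `n_targets`.
#' @export
summarize_behaviour <- function(schedule, include_practice = FALSE) {
  s <- schedule
  if (!include_practice) s <- s[!s$is_practice, ]
  cells <- unique(s[, c("condition", "block")])
  cells <- cells[order(cells$condition, cells$block), ]
  res <- lapply(seq_len(nrow(cells)), function(i) {
    b <- s[s$condition == cells$condition[i] & s$block == cells$block[i], ]
    tg <- b[b$role == "target" & b$colour == "cued", ]
    n_t <- nrow(tg)
    miss_rate <- if (n_t > 0) mean(tg$outcome == "miss") else NA_real_
    rt <- b$rt_ms[b$outcome == "hit"]
    data.frame(condition = cells$condition[i], block = cells$block[i],
               n_targets = n_t, miss_rate = miss_rate,
               undefined = n_t == 0,
               mean_correct_rt_ms = if (length(rt)) mean(rt) else NA_real_)
  })
  do.call(rbind, res)
}

#' Early/late block sets for the time-on-task factor
#'
#' With the full 15-block design this is blocks 1-5 (early) versus 11-15
#' (late); shorter designs fall back to the first versus second half.
#'
#' @param n_blocks Blocks per condition.
#' @return List with `early` and `late` block index vectors.
#' @export
default_halves <- function(n_blocks) {
  if (n_blocks >= 10) {
    list(early = 1:5, late = (n_blocks - 4):n_blocks)
  } else {
    h <- floor(n_blocks / 2)
    list(early = seq_len(h), late = seq(n_blocks - h + 1, n_blocks))
  }
}

#' Bayes-factor test of the behavioural vigilance-decrement interaction
#'
#' For each subject's behavioural summary, computes the late-minus-early
#' change in miss rate separately for Monitoring and Active blocks and
#' tests the condition difference of those changes (a time-on-task by
#' target-frequency interaction) with a one-sample JZS Bayes-factor t-test
#' across subjects.
#'
#' @param summaries List of per-subject outputs of [summarize_behaviour()].
#' @param early_blocks,late_blocks Block indices defining early / late.
#' @return List with `bf10`, per-subject interaction scores `delta`, and
#'   the evidence `category` (see [interpret_bf()]).
#' @export
behaviour_interaction_bf <- function(summaries, early_blocks = 1:5,
                                     late_blocks = 11:15) {
  delta <- vapply(summaries, function(su) {
    d_cond <- function(cond) {
      e <- su$miss_rate[su$condition == cond & su$block %in% early_blocks]
      l <- su$miss_rate[su$condition == cond & su$block %in% late_blocks]
      mean(l, na.rm = TRUE) - mean(e, na.rm = TRUE)
    }
    d_cond("monitoring") - d_cond("active")
  }, numeric(1))
  bf <- jzs_bf_ttest(delta)
  list(bf10 = bf$bf10, delta = delta, category = interpret_bf(bf$bf10))
}

#' Block-wise Active-vs-Monitoring Bayes factors
#'
#' Paired JZS Bayes-factor t-tests contrasting the two target-frequency
#' conditions block by block across subjects, for miss rate or correct RT.
#'
#' @param summaries List of per-subject [summarize_behaviour()] tables.
#' @param measure `"miss_rate"` or `"mean_correct_rt_ms"`.
#' @return data.frame with `block`, `bf10`, `category`, and the per-block
#'   condition means.
#' @export
blockwise_condition_bf <- function(summaries, measure = c("miss_rate", "mean_correct_rt_ms")) {
  measure <- match.arg(measure)
  blocks <- sort(unique(summaries[[1]]$block))
  res <- lapply(blocks, function(b) {
    act <- vapply(summaries, function(su) su[[measure]][su$condition == "active" & su$block == b], numeric(1))
    mon <- vapply(summaries, function(su) su[[measure]][su$condition == "monitoring" & su$block == b], numeric(1))
    ok <- is.finite(act) & is.finite(mon)
    bf <- if (sum(ok) >= 2 && sd(mon[ok] - act[ok]) > 0) {
      jzs_bf_ttest(mon[ok], act[ok], paired = TRUE)$bf10
    } else NA_real_
    data.frame(block = b, mean_active = mean(act[ok]), mean_monitoring = mean(mon[ok]),
               bf10 = bf, category = if (is.na(bf)) NA_character_ else interpret_bf(bf))
  })
  do.call(rbind, res)
}
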