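test_that("schedules respect the task's exact design counts", {
  sch <- generate_schedule(task_config(), seed = 42)
  main <- sch[!sch$is_practice, ]

  expect_equal(nrow(main), 1920)
  expect_equal(length(unique(paste(main$condition, main$block))), 30)

  per_block <- table(main$condition, main$block)
  expect_true(all(per_block == 64))

  for (cond in c("active", "monitoring")) {
    b1 <- main[main$condition == cond & main$block == 1, ]
    expect_equal(sum(b1$colour == "cued"), 32)
    expect_equal(sum(b1$colour == "noncued"), 32)
    n_t <- if (cond == "active") 16 else 2
    expect_equal(sum(b1$role == "target"), n_t)
    expect_true(all(b1$colour[b1$role == "target"] == "cued"))
    expect_equal(sum(b1$role == "distractor_event"), n_t)
    expect_true(all(b1$colour[b1$role == "distractor_event"] == "noncued"))
  }

  expect_true(all(sch$onset_ms >= 0 & sch$onset_ms < 110 * 1000))
  expect_true(all(sch$deflection_ms < sch$collision_ms))

  # directions approximately balanced within each block
  dir_split <- tapply(main$direction == "left", paste(main$condition, main$block), mean)
  expect_true(all(abs(dir_split - 0.5) < 0.01))
})

test_that("schedule generation is deterministic and validates its config", {
  a <- generate_schedule(task_config(), seed = 7)
  b <- generate_schedule(task_config(), seed = 7)
  expect_identical(a, b)
  c <- generate_schedule(task_config(), seed = 8)
  expect_false(identical(a, c))

  # degenerate: no targets at all
  z <- generate_schedule(task_config(targets_active = 0, targets_monitoring = 0), 1)
  expect_true(all(z$role %in% c("event")))

  expect_error(generate_schedule(task_config(block_duration_s = 5), 1),
               "scheduling error")
  expect_error(task_config(dots_per_colour = 30), "dots_per_colour")
  expect_error(task_config(targets_monitoring = 20), "targets_monitoring")
})

test_that("behavioural simulation follows the outcome model", {
  cfg <- task_config(n_blocks_per_condition = 6)
  sch <- generate_schedule(cfg, 3)

  # perfect observer: every target hit, no false alarms
  perfect <- behaviour_model(base_miss_prob = 0, base_miss_active = 0,
                             vigilance_slope = 0, active_learning_slope = 0,
                             active_plateau = 0, fa_rate = 0)
  out <- simulate_behaviour(sch, perfect, 4)
  tg <- out[out$role == "target" & out$colour == "cued", ]
  expect_true(all(tg$outcome == "hit"))
  expect_false(any(grepl("false_alarm", out$outcome)))
  su <- summarize_behaviour(out)
  expect_true(all(su$miss_rate == 0))

  # hit RTs land inside the deflection-to-collision window
  hits <- out[out$outcome == "hit", ]
  expect_true(all(hits$rt_ms > 0))
  expect_true(all(hits$rt_ms <= hits$collision_ms - hits$deflection_ms))

  # outcomes only on legal roles
  expect_true(all(out$outcome[out$outcome %in% c("hit", "miss")] %in% c("hit", "miss")))
  expect_true(all(out$role[out$outcome %in% c("hit", "miss")] == "target"))
  expect_true(all(out$colour[out$outcome %in% c("hit", "miss")] == "cued"))
})

test_that("flat behaviour model shows no block trend; sloped model does", {
  cfg <- task_config()
  flat <- behaviour_model(base_miss_prob = 0.3, base_miss_active = 0.3,
                          vigilance_slope = 0, active_learning_slope = 0,
                          active_plateau = 0)
  # pool many subjects so per-block rates are stable
  rates <- sapply(1:12, function(s) {
    out <- simulate_behaviour(generate_schedule(cfg, s), flat, 100 + s)
    su <- summarize_behaviour(out)
    su$miss_rate[su$condition == "monitoring"]
  })
  trend <- coef(lm(rowMeans(rates) ~ seq_len(nrow(rates))))[2]
  expect_lt(abs(trend), 0.01)

  # default model: monitoring rises, active falls then plateaus
  blocks <- 1:15
  p_mon <- miss_probability(behaviour_model(), blocks, "monitoring")
  p_act <- miss_probability(behaviour_model(), blocks, "active")
  expect_true(all(diff(p_mon) > 0))
  expect_true(all(diff(p_act) <= 0))
  expect_equal(min(p_act), behaviour_model()$active_plateau)
  expect_gt(p_mon[15], p_act[15])
})

test_that("behavioural summary reports per-block rates and flags empty blocks", {
  sch <- data.frame(
    condition = "monitoring", block = c(1, 1, 2), is_practice = FALSE,
    onset_ms = 0, colour = "cued", direction = "left",
    role = c("target", "target", "event"),
    deflection_ms = 1226, collision_ms = 1636,
    outcome = c("hit", "miss", "correct_reject"), rt_ms = c(200, NA, NA))
  su <- summarize_behaviour(sch)
  expect_equal(su$miss_rate[su$block == 1], 0.5)
  expect_true(is.na(su$miss_rate[su$block == 2]))
  expect_true(su$undefined[su$block == 2])
  expect_equal(su$mean_correct_rt_ms[su$block == 1], 200)
})

test_that("epoch simulation is seed-deterministic and labels are consistent", {
  sub1 <- small_subject(5, n_blocks = 2, max_trials = 20)
  sub2 <- small_subject(5, n_blocks = 2, max_trials = 20)
  expect_identical(sub1$epochs$data, sub2$epochs$data)
  expect_identical(sub1$epochs$labels, sub2$epochs$labels)

  lab <- sub1$epochs$labels
  expect_setequal(unique(lab$direction), c("left", "right"))
  expect_identical(lab$attended, lab$colour == "cued")
  expect_true(all(lab$deflection_ms > 0 & lab$deflection_ms <= 3000))
})

test_that("noise-free direction signal decodes perfectly after onset", {
  sm <- small_sensors(n_sensors = 8, noise_sd = 0, attention_gain = 1,
                      dist_strength = 0, dir_amp_sd = 0)
  sub <- small_subject(2, n_blocks = 1, sensors = sm, max_trials = 40)
  res <- decode_direction_timecourse(sub$epochs, n_folds = 5, seed = 3)
  post <- res$accuracy[res$time_ms > 200 & res$time_ms < 1000]
  expect_true(all(post == 1))
  # no signal exists before onset: chance there
  pre <- res$accuracy[res$time_ms < 0]
  expect_lt(abs(mean(pre) - 0.5), 0.15)
})
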