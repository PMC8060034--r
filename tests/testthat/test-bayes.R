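# reference values computed independently with pingouin.bayesfactor_ttest
# (JZS prior, r = sqrt(2)/2) and frozen here
test_that("JZS t-test Bayes factors match independent reference values", {
  expect_equal(momdecode:::jzs_bf10_from_t(0, 21, 20), 0.22748761, tolerance = 1e-6)
  expect_equal(momdecode:::jzs_bf10_from_t(2.5, 21, 20), 2.71048477, tolerance = 1e-6)
  expect_equal(momdecode:::jzs_bf10_from_t(8, 21, 20), 129676.99, tolerance = 1e-4)
  expect_equal(momdecode:::jzs_bf10_from_t(1, 10, 9), 0.46487301, tolerance = 1e-6)
  # two-sample: n_eff = n1 n2 / (n1 + n2)
  expect_equal(momdecode:::jzs_bf10_from_t(3, 21 * 1000 / 1021, 1019),
               12.1765030, tolerance = 1e-5)

  # a null-consistent sample at n = 21 gives moderate evidence for the null
  expect_lt(momdecode:::jzs_bf10_from_t(0, 21, 20), 1 / 3)
  # a huge effect gives strong evidence for the alternative
  expect_gt(momdecode:::jzs_bf10_from_t(8, 21, 20), 10)
})

test_that("JZS Bayes factor is scale invariant, reciprocal and monotone in |t|", {
  with_seed_test(1, {
    x <- rnorm(21, 0.3); y <- rnorm(21, 0)
  })
  a <- jzs_bf_ttest(x, y)
  expect_equal(jzs_bf_ttest(1000 * x, 1000 * y)$bf10, a$bf10, tolerance = 1e-8)
  expect_equal(a$bf10 * a$bf01, 1)
  expect_equal(jzs_bf_ttest(y, x)$bf10, a$bf10, tolerance = 1e-8)

  bfs <- vapply(c(0, 0.5, 1, 2, 4, 8),
                function(t) momdecode:::jzs_bf10_from_t(t, 21, 20), numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_equal(momdecode:::jzs_bf10_from_t(-3, 21, 20),
               momdecode:::jzs_bf10_from_t(3, 21, 20), tolerance = 1e-9)

  expect_error(jzs_bf_ttest(rep(1, 10)), "zero variance")
  expect_error(jzs_bf_ttest(1), "n >= 2")
  # paired test equals the one-sample test of differences
  p <- jzs_bf_ttest(x, y, paired = TRUE)
  expect_equal(p$bf10, jzs_bf_ttest(x - y)$bf10)
})

test_that("Bayes factors are categorized at the 10, 3, 1/3, 1/10 thresholds", {
  expect_equal(interpret_bf(12), "strong_alt")
  expect_equal(interpret_bf(5), "moderate_alt")
  expect_equal(interpret_bf(1), "insufficient")
  expect_equal(interpret_bf(0.2), "moderate_null")
  expect_equal(interpret_bf(0.05), "strong_null")
  expect_error(interpret_bf(-1))
})

test_that("shuffled-null comparison finds shifts and respects its seed", {
  null_fn <- function(seed) with_seed_test(seed, 0.5 + rnorm(1, 0, 0.03))
  with_seed_test(2, actual <- 0.65 + rnorm(21, 0, 0.03))
  res <- bf_vs_shuffled_null(actual, null_fn, n_perm = 200, seed = 5)
  expect_gt(res$bf10, 10)
  expect_identical(bf_vs_shuffled_null(actual, null_fn, 200, seed = 5)$bf10,
                   res$bf10)

  # actual drawn from the null itself: no evidence for a difference
  with_seed_test(3, like_null <- 0.5 + rnorm(21, 0, 0.03))
  expect_lt(bf_vs_shuffled_null(like_null, null_fn, 200, seed = 6)$bf10, 1)
})

test_that("under the null, strong t-test Bayes factors are rare", {
  bfs <- vapply(1:200, function(i) {
    with_seed_test(1000 + i, jzs_bf_ttest(rnorm(21))$bf10)
  }, numeric(1))
  expect_lt(mean(bfs > 3), 0.05)
})

make_anova_table <- function(att_eff = 0, freq_eff = 0, inter = 0, sd = 0.3,
                             seed = 1, n = 21) {
  with_seed_test(seed, {
    g <- expand.grid(subject = sprintf("s%02d", 1:n),
                     attention = c("att", "unatt"),
                     frequency = c("act", "mon"),
                     half = c("early", "late"), stringsAsFactors = FALSE)
    subj <- rnorm(n, 0, 0.5); names(subj) <- sprintf("s%02d", 1:n)
    g$value <- subj[g$subject] + att_eff * (g$attention == "att") +
      freq_eff * (g$frequency == "mon") +
      inter * (g$attention == "att") * (g$frequency == "mon") +
      rnorm(nrow(g), 0, sd)
    g
  })
}

test_that("BF ANOVA recovers a pure additive effect and rejects absent ones", {
  d <- make_anova_table(att_eff = 0.5, seed = 10)
  expect_gt(bf_anova_effect(d, "attention")$bf10, 3)
  expect_lt(bf_anova_effect(d, "frequency")$bf10, 1 / 3)

  # pure-noise table: no effect wins
  d0 <- make_anova_table(seed = 11)
  for (eff in c("attention", "frequency", "half")) {
    expect_lt(bf_anova_effect(d0, eff)$bf10, 1)
  }
})

test_that("permuting condition labels within subject destroys the effect", {
  d <- make_anova_table(att_eff = 0.5, seed = 12)
  dp <- d
  with_seed_test(13, {
    for (s in unique(d$subject)) {
      rows <- which(d$subject == s)
      dp$value[rows] <- d$value[sample(rows)]
    }
  })
  expect_gt(bf_anova_effect(d, "attention")$bf10, 3)
  expect_lt(bf_anova_effect(dp, "attention")$bf10, 3)
})

test_that("BF ANOVA is seeded-deterministic and validates its design", {
  d <- make_anova_table(att_eff = 0.3, seed = 14)
  a <- bf_anova_effect(d, "attention", seed = 3)
  expect_identical(bf_anova_effect(d, "attention", seed = 3)$bf10, a$bf10)
  # interaction names are order-insensitive
  x <- bf_anova_effect(d, "frequency:attention", seed = 3)
  y <- bf_anova_effect(d, "attention:frequency", seed = 3)
  expect_identical(x$bf10, y$bf10)

  expect_error(bf_anova_effect(d[-1, ], "attention"), "balanced")
  expect_error(bf_anova_effect(d, "colour"), "unknown effect")
  d_na <- d; d_na$value[3] <- NA
  expect_error(bf_anova_effect(d_na, "attention"), "missing")
})
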