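#' JZS Bayes-factor t-test
#'
#' Bayes factor (alternative over null) for one- and two-sample t-tests
#' under the Jeffreys-Zellner-Siow prior: a Cauchy prior with scale `r` on
#' the standardized effect size and Jeffreys priors on nuisance
#' parameters. Computed by one-dimensional quadrature over the
#' variance-mixing parameter of the Cauchy (an inverse-gamma(1/2, r^2/2)
#' scale mixture of normals); deterministic given the data and `r`. The
#' result is invariant under rescaling of the measurement units.
#'
#' @param x Numeric sample (or first sample).
#' @param y Optional second sample (two-sample test, or paired when
#'   `paired = TRUE`).
#' @param mu0 Null value for the one-sample test.
#' @param paired Treat `x`, `y` as paired and test `x - y`.
#' @param r Cauchy prior scale (default `sqrt(2)/2`).
#' @return List with `bf10`, `bf01`, `t`, `df`, `n_eff`, `category`
#'   (see [interpret_bf()]).
#' @export
jzs_bf_ttest <- function(x, y = NULL, mu0 = 0, paired = FALSE, r = sqrt(2) / 2) {
  if (paired) {
    stopifnot(!is.null(y), length(x) == length(y))
    x <- x - y; y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2) stop("need n >= 2")
    if (sd(x) == 0) stop("zero variance sample: t statistic undefined")
    t_stat <- (mean(x) - mu0) / (sd(x) / sqrt(n))
    n_eff <- n; df <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2 || n2 < 2) stop("need n >= 2 per sample")
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) stop("zero variance samples: t statistic undefined")
    t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  bf10 <- jzs_bf10_from_t(t_stat, n_eff, df, r)
  list(bf10 = bf10, bf01 = 1 / bf10, t = t_stat, df = df, n_eff = n_eff,
       category = interpret_bf(bf10))
}

# BF10 from a t statistic (Rouder et al. default Bayes factor):
# numerator integrates the alternative's likelihood over g with
# g ~ InverseGamma(1/2, r^2/2); denominator is the null likelihood.
jzs_bf10_from_t <- function(t_stat, n_eff, df, r = sqrt(2) / 2) {
  log_null <- -(df + 1) / 2 * log1p(t_stat^2 / df)
  integrand <- function(g) {
    log_alt <- -0.5 * log1p(n_eff * g) -
      (df + 1) / 2 * log1p(t_stat^2 / ((1 + n_eff * g) * df))
    log_prior <- 0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g)
    exp(log_alt + log_prior - log_null)
  }
  val <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-9,
                          stop.on.error = FALSE)
  if (!val$value > 0) stop("JZS quadrature failed (t = ", t_stat, ")")
  val$value
}

#' Categorize a Bayes factor
#'
#' Thresholds at 10, 3, 1/3 and 1/10: BF10 > 10 strong and > 3 moderate
#' evidence for the alternative; < 1/10 strong and < 1/3 moderate evidence
#' for the null; in between, insufficient evidence.
#'
#' @param bf10 Positive Bayes factor (alternative over null).
#' @return One of `"strong_alt"`, `"moderate_alt"`, `"insufficient"`,
#'   `"moderate_null"`, `"strong_null"`.
#' @export
interpret_bf <- function(bf10) {
  stopifnot(bf10 > 0)
  if (bf10 > 10) "strong_alt"
  else if (bf10 > 3) "moderate_alt"
  else if (bf10 >= 1 / 3) "insufficient"
  else if (bf10 >= 1 / 10) "moderate_null"
  else "strong_null"
}

#' Bayes factor of observed accuracies against a shuffled-label null
#'
#' Builds an empirical null by re-running a decoding callback on
#' label-permuted data (`n_perm` seeded shuffles) and compares the
#' distribution of observed per-subject accuracies against the null
#' accuracies with the two-sample JZS machinery.
#'
#' @param actual Per-subject observed accuracies.
#' @param null_fn Callback `function(seed)` returning one accuracy under
#'   label permutation.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Master seed; permutation `i` uses `derive_seed(seed, i)`.
#' @param r Cauchy prior scale.
#' @return List with `bf10`, `null` (the permuted accuracies), `category`.
#' @export
bf_vs_shuffled_null <- function(actual, null_fn, n_perm = 1000L, seed = 1L,
                                r = sqrt(2) / 2) {
  null <- vapply(seq_len(n_perm), function(i) null_fn(derive_seed(seed, "perm", i)),
                 numeric(1))
  if (anyNA(null)) stop("null generation failed: callback returned NA")
  bf <- jzs_bf_ttest(actual, null, r = r)
  list(bf10 = bf$bf10, t = bf$t, null = null, category = interpret_bf(bf$bf10))
}

#' Bayes-factor ANOVA for one effect (full vs restricted model)
#'
#' Model-comparison Bayes factor for a named main effect or interaction in
#' a within-subject 2 x 2 x 2 design (attention x target frequency x
#' time-on-task), with subject as an additive random factor in every
#' model. Each candidate model places zero-centred g-priors on its
#' sum-to-zero effect columns (scale `r_fixed` for condition effects,
#' `r_random` for subject effects) and Jeffreys priors on the grand mean
#' and error variance; marginal likelihoods are obtained by seeded Monte
#' Carlo integration over the per-term g parameters. The reported BF is
#' the evidence ratio of the full model (all terms) to the restricted
#' model (all terms except the one under evaluation).
#'
#' @param data data.frame with columns `subject`, `value`, and the factor
#'   columns named in `factors`.
#' @param effect Effect name: a factor name or an interaction such as
#'   `"attention:frequency"` (order-insensitive).
#' @param factors Character vector of the design factors present in `data`.
#' @param n_mc Monte Carlo samples for the g integration.
#' @param seed Integer seed (same seed is used for full and restricted
#'   models so shared terms' noise cancels).
#' @param r_fixed,r_random Prior scales.
#' @return List with `bf10` (full vs restricted), `bf_full`, `bf_restricted`
#'   (each vs the subject-only null), `effect`, `category`.
#' @export
bf_anova_effect <- function(data, effect,
                            factors = c("attention", "frequency", "half"),
                            n_mc = 4000L, seed = 1L,
                            r_fixed = 0.5, r_random = 1) {
  stopifnot(all(c("subject", "value", factors) %in% names(data)))
  if (anyNA(data$value)) stop("missing cells in the design table")
  cells <- table(data$subject, interaction(data[factors]))
  if (any(cells != 1)) stop("design must be balanced: one value per subject per cell")

  all_terms <- design_terms(factors)
  effect <- normalize_term(effect, factors)
  if (!(effect %in% all_terms)) stop("unknown effect: ", effect)
  restricted <- setdiff(all_terms, effect)

  bf_full <- bf_model_vs_null(data, all_terms, factors, n_mc, seed, r_fixed, r_random)
  bf_res <- bf_model_vs_null(data, restricted, factors, n_mc, seed, r_fixed, r_random)
  bf10 <- bf_full / bf_res
  list(bf10 = bf10, bf_full = bf_full, bf_restricted = bf_res,
       effect = effect, category = interpret_bf(bf10))
}

design_terms <- function(factors) {
  unlist(lapply(seq_along(factors), function(k) {
    apply(utils::combn(factors, k), 2, paste, collapse = ":")
  }))
}

normalize_term <- function(effect, factors) {
  parts <- strsplit(effect, ":")[[1]]
  paste(factors[sort(match(parts, factors))], collapse = ":")
}

# sum-to-zero design column(s) for a term ("a" or "a:b" ...)
term_columns <- function(data, term) {
  parts <- strsplit(term, ":")[[1]]
  cols <- lapply(parts, function(f) {
    lev <- sort(unique(data[[f]]))
    stats::contr.sum(length(lev))[match(data[[f]], lev), , drop = FALSE]
  })
  Reduce(function(a, b) {
    do.call(cbind, lapply(seq_len(ncol(a)), function(i) a[, i] * b))
  }, cols)
}

# BF(model-with-terms vs intercept-only) by Monte Carlo over per-group g's.
# Subject is always included as a random term.
bf_model_vs_null <- function(data, terms, factors, n_mc, seed, r_fixed, r_random) {
  y <- data$value
  n <- length(y)
  subj <- factor(data$subject)
  Zs <- stats::model.matrix(~ subj - 1)
  Zs <- Zs - 1 / nlevels(subj)                 # centred random-effect columns
  blocks <- c(lapply(terms, function(tm) term_columns(data, tm)),
              list(subject = Zs))
  r_scales <- c(rep(r_fixed, length(terms)), r_random)
  W <- do.call(cbind, blocks)
  block_id <- rep(seq_along(blocks), vapply(blocks, ncol, integer(1)))

  WtW <- crossprod(W)
  Wty <- crossprod(W, y)
  Wt1 <- crossprod(W, rep(1, n))
  yy <- sum(y^2); ybar <- mean(y)
  log_m0 <- -0.5 * log(n) - (n - 1) / 2 * log(yy - n * ybar^2)

  k <- ncol(W)
  with_seed(seed, {
    logbf <- vapply(seq_len(n_mc), function(i) {
      g <- 1 / stats::rgamma(length(blocks), shape = 0.5, rate = r_scales^2 / 2)
      sg <- sqrt(g[block_id])
      A <- diag(k) + (sg %o% sg) * WtW
      R <- chol(A)
      solve_A <- function(v) backsolve(R, forwardsolve(t(R), v))
      wy <- sg * Wty; w1 <- sg * Wt1
      q_yy <- yy - sum(wy * solve_A(wy))
      q_y1 <- n * ybar - sum(w1 * solve_A(wy))
      q_11 <- n - sum(w1 * solve_A(w1))
      logdet <- 2 * sum(log(diag(R)))
      log_m <- -0.5 * logdet - 0.5 * log(q_11 / n) - 0.5 * log(n) -
        (n - 1) / 2 * log(q_yy - q_y1^2 / q_11)
      log_m - log_m0
    }, numeric(1))
    off <- max(logbf)
    exp(off) * mean(exp(logbf - off))
  })
}
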