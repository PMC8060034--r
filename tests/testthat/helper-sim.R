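# shared small-scale fixtures, all generated in code

# compact task: fewer blocks, same within-block structure
small_task <- function(n_blocks = 4) {
  task_config(n_blocks_per_condition = n_blocks, practice_blocks = 1)
}

# compact sensor model generating directly at 200 Hz; noise scaled so the
# reduced sensor count keeps a similar multivariate SNR to the default
small_sensors <- function(n_sensors = 24, noise_sd = 6, ...) {
  sensor_model(n_sensors = n_sensors, fs_hz = 200, noise_sd = noise_sd, ...)
}

# one simulated subject at test scale; epochs for a trial subset only
small_subject <- function(seed = 1, n_blocks = 4, sensors = small_sensors(),
                          behaviour = behaviour_model(), max_trials = Inf,
                          attended_only = FALSE) {
  cfg <- small_task(n_blocks)
  sch <- generate_schedule(cfg, derive_seed(seed, "sch"))
  sch <- simulate_behaviour(sch, behaviour, derive_seed(seed, "beh"))
  trials <- which(!sch$is_practice)
  if (attended_only) trials <- trials[sch$colour[trials] == "cued"]
  if (length(trials) > max_trials) {
    trials <- with_seed_test(derive_seed(seed, "sub"),
                             sort(sample(trials, max_trials)))
  }
  eb <- 1:ceiling(n_blocks / 2); lb <- setdiff(1:n_blocks, eb)
  ep <- simulate_epochs(sch, sensors, derive_seed(seed, "ep"), trials = trials,
                        early_blocks = eb, late_blocks = lb)
  list(schedule = sch, epochs = ep)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# epoch set built directly from an array, for binning/decoding unit tests
toy_epochs <- function(data, fs_hz = 200, t0 = -100, labels = NULL) {
  n <- dim(data)[1]
  time_ms <- t0 + (seq_len(dim(data)[3]) - 1) * 1000 / fs_hz
  if (is.null(labels)) {
    labels <- data.frame(direction = rep(c("left", "right"), length.out = n),
                         deflection_ms = rep(1226, n))
  }
  epoch_set(data, time_ms, fs_hz, labels)
}

# two-class Gaussian toy features
toy_gaussian <- function(n_per_class, p, delta, sd = 1, seed = 1) {
  with_seed_test(seed, {
    x <- rbind(matrix(rnorm(n_per_class * p, 0, sd), n_per_class),
               matrix(rnorm(n_per_class * p, delta, sd), n_per_class))
    list(x = x, y = rep(c("a", "b"), each = n_per_class))
  })
}

# brute-force two-class Gaussian classifier: explicit inversion of the
# pooled (shrunk) covariance and direct density comparison; independent of
# the package's LDA code path
brute_force_gaussian_predict <- function(xtr, ytr, xte, lambda) {
  classes <- unique(ytr)
  m1 <- colMeans(xtr[ytr == classes[1], , drop = FALSE])
  m2 <- colMeans(xtr[ytr == classes[2], , drop = FALSE])
  r1 <- sweep(xtr[ytr == classes[1], , drop = FALSE], 2, m1)
  r2 <- sweep(xtr[ytr == classes[2], , drop = FALSE], 2, m2)
  S <- (crossprod(r1) + crossprod(r2)) / (nrow(xtr) - 2)
  p <- ncol(S)
  Sh <- (1 - lambda) * S + diag(lambda * mean(diag(S)) + 1e-10 * max(mean(diag(S)), 1e-12), p)
  Si <- solve(Sh)
  d1 <- apply(xte, 1, function(v) -0.5 * t(v - m1) %*% Si %*% (v - m1))
  d2 <- apply(xte, 1, function(v) -0.5 * t(v - m2) %*% Si %*% (v - m2))
  ifelse(d1 >= d2, classes[1], classes[2])
}
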