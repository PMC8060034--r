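#' Fit a two-class shrinkage LDA classifier
#'
#' Closed-form linear discriminant analysis for two classes: class means
#' plus a pooled covariance shrunk towards its identity-scaled diagonal
#' average. The shrinkage intensity is either a fixed value in \[0, 1\] or
#' `"auto"`, the analytic (Ledoit-Wolf) estimate computed from the pooled
#' within-class residuals. Deterministic given its inputs.
#'
#' @param x Numeric matrix, trials x features.
#' @param y Two-class label vector (first unique value is "class 0", the
#'   class assigned on a tied discriminant score).
#' @param shrinkage `"auto"` or a numeric in \[0, 1\].
#' @return An `lda_model` with `class_means`, `covariance` (shrunk),
#'   `chol` factor, `lambda`, `classes`.
#' @export
fit_lda <- function(x, y, shrinkage = "auto") {
  x <- as.matrix(x)
  classes <- unique(y)
  if (length(classes) != 2) stop("fit_lda requires exactly two classes, got ", length(classes))
  i1 <- which(y == classes[1]); i2 <- which(y == classes[2])
  if (length(i1) < 2 || length(i2) < 2) stop("need at least 2 trials per class")

  m1 <- colMeans(x[i1, , drop = FALSE])
  m2 <- colMeans(x[i2, , drop = FALSE])
  resid <- rbind(sweep(x[i1, , drop = FALSE], 2, m1),
                 sweep(x[i2, , drop = FALSE], 2, m2))
  n <- nrow(resid); p <- ncol(resid)
  SS <- crossprod(resid)
  S <- SS / (n - 2)

  lambda <- if (identical(shrinkage, "auto")) ledoit_wolf_lambda(resid, SS / n) else {
    stopifnot(is.numeric(shrinkage), shrinkage >= 0, shrinkage <= 1)
    shrinkage
  }
  nu <- mean(diag(S))
  Sh <- (1 - lambda) * S
  diag(Sh) <- diag(Sh) + lambda * nu
  # guarantee positive definiteness even at lambda = 0 on degenerate input
  R <- tryCatch(chol(Sh), error = function(e) {
    diag(Sh) <- diag(Sh) + 1e-8 * max(nu, 1e-12)
    chol(Sh)
  })
  structure(list(class_means = rbind(m1, m2), covariance = Sh, chol = R,
                 lambda = lambda, classes = classes, p = p),
            class = "lda_model")
}

# Ledoit-Wolf (2004) intensity for shrinkage towards mean(diag(S)) * I,
# computed on centred within-class residuals. Returns lambda in [0, 1].
# Uses sum_k x_k' Sn x_k = n * tr(Sn^2), so no extra matrix product is
# needed beyond the scatter itself.
ledoit_wolf_lambda <- function(resid, Sn = NULL) {
  n <- nrow(resid); p <- ncol(resid)
  if (is.null(Sn)) Sn <- crossprod(resid) / n
  mu <- sum(diag(Sn)) / p
  fro <- sum(Sn^2)
  d2 <- (fro - p * mu^2) / p
  if (d2 < .Machine$double.eps) return(0)
  q <- rowSums(resid^2)                   # x_k' x_k
  b2bar <- (sum(q^2) - n * fro) / (n^2 * p)
  min(max(b2bar, 0), d2) / d2
}

#' Predict with a fitted LDA model
#'
#' @param object An `lda_model`.
#' @param newdata Matrix of trials x features.
#' @param ... Unused.
#' @return Vector of predicted class labels; a tied (exactly zero)
#'   discriminant score goes to the first class.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  sc <- lda_scores(object, as.matrix(newdata))
  ifelse(sc >= 0, object$classes[1], object$classes[2])
}

# signed discriminant: positive -> first class
lda_scores <- function(model, x) {
  w <- backsolve(model$chol, forwardsolve(t(model$chol), model$class_means[1, ] - model$class_means[2, ]))
  c0 <- sum(w * (model$class_means[1, ] + model$class_means[2, ]) / 2)
  drop(x %*% w) - c0
}

# Fast internal path: train on (xtr, y01 in {0,1}; 0 = first class) and
# return 0/1 correctness of `xte` against `yte01`.
lda_train_correct <- function(xtr, y01, xte, yte01, shrinkage = "auto") {
  i1 <- which(y01 == 0L); i2 <- which(y01 == 1L)
  x1 <- xtr[i1, , drop = FALSE]; x2 <- xtr[i2, , drop = FALSE]
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  resid <- rbind(x1 - rep(m1, each = nrow(x1)),
                 x2 - rep(m2, each = nrow(x2)))
  n <- nrow(resid); p <- ncol(resid)
  SS <- crossprod(resid)
  lambda <- if (identical(shrinkage, "auto")) ledoit_wolf_lambda(resid, SS / n) else shrinkage
  Sh <- SS * ((1 - lambda) / (n - 2))
  nu <- sum(diag(SS)) / ((n - 2) * p)
  diag(Sh) <- diag(Sh) + lambda * nu + 1e-10 * max(nu, 1e-12)
  R <- chol(Sh)
  w <- backsolve(R, forwardsolve(R, m1 - m2, upper.tri = TRUE, transpose = TRUE))
  sc <- drop(xte %*% w) - sum(w * (m1 + m2) / 2)
  pred <- as.integer(sc < 0)            # tie (sc == 0) -> class 0
  as.integer(pred == yte01)
}

#' Allocate trials to cross-validation folds
#'
#' Random fold assignment at the trial level: all samples derived from a
#' trial share its fold, so training and testing never mix samples of the
#' same trial.
#'
#' @param n_trials Number of trials.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..n_folds) per trial.
#' @export
make_folds <- function(n_trials, n_folds = 10L, seed = 1L) {
  if (n_trials < n_folds) {
    stop("fewer trials (", n_trials, ") than folds (", n_folds, ")")
  }
  with_seed(seed, sample(rep(seq_len(n_folds), length.out = n_trials)))
}
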