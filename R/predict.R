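#' Ridge regression by the normal equations
#'
#' Features are standardized by training statistics (population variance);
#' the weights solve `(X'X + alpha I) w = X'(y - mean(y))` on the
#' standardized design and the intercept is `mean(y)`, so predictions are
#' invariant to affine rescaling of the input features.  Zero-variance
#' features are dropped with a warning.
#'
#' @param X subject x feature numeric matrix (n >= 2).
#' @param y per-subject trait.
#' @param alpha nonnegative ridge penalty (default 1 on standardized
#'   features).
#' @param standardize standardize features by training statistics.
#' @return a `RidgeFit`.
#' @export
fit_ridge <- function(X, y, alpha = 1, standardize = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 training samples")
  if (alpha < 0) stop("alpha must be nonnegative")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu, "-")^2))
  keep <- which(sdv > 0)
  if (length(keep) < ncol(X))
    warning("dropped ", ncol(X) - length(keep), " zero-variance feature(s)")
  if (!standardize) { mu[] <- 0; sdv[] <- 1 }
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep], "-"), 2,
              pmax(sdv[keep], if (standardize) -Inf else 1), "/")
  yc <- y - mean(y)
  # solve via SVD: stable for ill-conditioned designs, and at alpha = 0 it
  # returns the minimum-norm least-squares solution, which still satisfies
  # the normal equations X'X w = X'y
  if (ncol(Xs) > 0) {
    sv <- svd(Xs)
    d <- sv$d
    filt <- if (alpha > 0) d / (d^2 + alpha)
            else ifelse(d > max(d) * 1e-10, 1 / d, 0)
    w <- sv$v %*% (filt * crossprod(sv$u, yc))
  } else w <- matrix(0, 0, 1)
  structure(list(weights = as.numeric(w), intercept = mean(y), alpha = alpha,
                 feature_means = mu[keep], feature_scales = sdv[keep],
                 kept = keep, n_features_in = ncol(X)),
            class = "RidgeFit")
}

#' Predict from a RidgeFit
#'
#' @param object a `RidgeFit`.
#' @param newdata matrix with the training feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.RidgeFit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features_in)
    stop("feature mismatch: model trained on ", object$n_features_in,
         " features, got ", ncol(newdata))
  Xs <- sweep(sweep(newdata[, object$kept, drop = FALSE], 2,
                    object$feature_means, "-"), 2, object$feature_scales, "/")
  as.numeric(Xs %*% object$weights) + object$intercept
}

#' Mean squared error of a fitted model on held-out data
#'
#' `MSE = (1/n) sum (y_i - yhat_i)^2`, with an optional per-run breakdown
#' when run ids are supplied (the evaluation design fits on run 1 and tests
#' on the remaining runs).
#'
#' @param fit a `RidgeFit`.
#' @param X_test,y_test held-out features and trait values.
#' @param run_ids optional run id per test row.
#' @return an `EvalResult`: `mse`, `per_run`, `predictions`.
#' @export
evaluate <- function(fit, X_test, y_test, run_ids = NULL) {
  yhat <- predict(fit, X_test)
  mse <- mean((y_test - yhat)^2)
  per_run <- NULL
  if (!is.null(run_ids)) {
    if (length(run_ids) != length(y_test)) stop("run_ids length mismatch")
    per_run <- tapply((y_test - yhat)^2, run_ids, mean)
  }
  structure(list(mse = mse, per_run = per_run, predictions = yhat),
            class = "EvalResult")
}

#' Chance baseline by training-label shuffling
#'
#' Refits the ridge model with permuted training labels `n_shuffles` times
#' and evaluates each on the untouched test set, giving the null (chance)
#' MSE distribution; also reports the quantile of the true MSE within it
#' (mid-rank convention for ties; small values mean the real model beats
#' chance).
#'
#' @param X_train,y_train training data.
#' @param X_test,y_test held-out data.
#' @param n_shuffles number of label permutations (>= 1).
#' @param seed integer seed.
#' @param alpha ridge penalty.
#' @return list with `chance_mse` (numeric vector), `true_mse`, `quantile`.
#' @export
chance_baseline <- function(X_train, y_train, X_test, y_test,
                            n_shuffles = 1000, seed = 1, alpha = 1) {
  if (n_shuffles < 1) stop("n_shuffles must be >= 1")
  true_fit <- suppressWarnings(fit_ridge(X_train, y_train, alpha = alpha))
  true_mse <- evaluate(true_fit, X_test, y_test)$mse
  chance <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    yp <- with_seed(substream_seed(seed, 11L, b), sample(y_train))
    fb <- suppressWarnings(fit_ridge(X_train, yp, alpha = alpha))
    chance[b] <- evaluate(fb, X_test, y_test)$mse
  }
  qtl <- (sum(chance < true_mse) + 0.5 * sum(chance == true_mse)) / n_shuffles
  list(chance_mse = chance, true_mse = true_mse, quantile = qtl)
}

#' Compare per-unit error vectors between conditions
#'
#' All condition pairs are compared on paired per-unit values (e.g. MSEs per
#' region or per subject).  `paired_t_bonferroni`: two-sided paired t test
#' with Bonferroni correction over the number of pairs (a constant nonzero
#' difference is guarded to statistic Inf, p = 0; a zero difference to t = 0,
#' p = 1).  `permutation_bh`: two-sided sign-flip permutation test of the
#' mean paired difference — exhaustive over all 2^n sign patterns when
#' `n <= 20`, otherwise `n_permutations` sampled flips — with
#' Benjamini-Hochberg step-up adjustment; `reject` applies the threshold
#' `q`.
#'
#' @param mse_by_condition named list: condition -> numeric vector, all of
#'   equal length.
#' @param method `"paired_t_bonferroni"` or `"permutation_bh"`.
#' @param n_permutations sampled sign flips when exhaustive enumeration is
#'   not feasible (the full-scale analysis uses 50,000).
#' @param q BH false-discovery threshold.
#' @param seed integer seed for sampled permutations.
#' @return data.frame: pair, statistic, p_raw, p_adjusted, reject.
#' @export
compare_conditions <- function(mse_by_condition,
                               method = c("paired_t_bonferroni", "permutation_bh"),
                               n_permutations = 10000, q = 0.05, seed = 1) {
  method <- match.arg(method)
  conds <- names(mse_by_condition)
  if (is.null(conds)) conds <- paste0("cond", seq_along(mse_by_condition))
  n <- unique(lengths(mse_by_condition))
  if (length(n) != 1) stop("condition vectors must have equal length")
  pairs <- utils::combn(seq_along(mse_by_condition), 2)
  out <- data.frame(pair = character(0), statistic = numeric(0),
                    p_raw = numeric(0))
  for (k in seq_len(ncol(pairs))) {
    a <- mse_by_condition[[pairs[1, k]]]
    b <- mse_by_condition[[pairs[2, k]]]
    d <- a - b
    if (method == "paired_t_bonferroni") {
      if (stats::sd(d) == 0) {
        stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        p <- if (mean(d) == 0) 1 else 0
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        stat <- unname(tt$statistic); p <- tt$p.value
      }
    } else {
      obs <- mean(d)
      nn <- length(d)
      if (nn <= 20) {
        signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), nn)))
        perm <- abs(signs %*% d / nn)
      } else {
        perm <- with_seed(substream_seed(seed, 12L, k), {
          vapply(seq_len(n_permutations), function(b2)
            abs(mean(d * sample(c(-1, 1), nn, replace = TRUE))), numeric(1))
        })
      }
      stat <- obs
      p <- mean(perm >= abs(obs) - 1e-15)
    }
    out <- rbind(out, data.frame(
      pair = paste(conds[pairs[1, k]], "vs", conds[pairs[2, k]]),
      statistic = stat, p_raw = p))
  }
  out$p_adjusted <- stats::p.adjust(
    out$p_raw, method = if (method == "paired_t_bonferroni") "bonferroni" else "BH")
  out$reject <- out$p_adjusted <= q
  out
}
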