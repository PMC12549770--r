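# Repeated, cross-validated ridge regression: model parameters vs
# behavioral summaries as predictors of age and symptom sums.

#' Assemble per-subject feature tables for prediction
#'
#' Feature set "parameters" = the 8 fitted RLWM-LBA parameters; feature
#' set "behavior" = accuracy per set size, overall accuracy, and mean
#' correct-trial RT per set size.
#'
#' @param params Data frame with `subject_id` and the 8 parameter
#'   columns (e.g. the `params` element of an `rlwm_fit`).
#' @param trials Cohort trial table.
#' @return List with matrices `parameters` and `behavior` (row names =
#'   subject ids, no missing values).
#' @export
feature_tables <- function(params, trials) {
  pm <- as.matrix(params[, rlwm_param_names()])
  rownames(pm) <- params$subject_id
  tr <- trials[!is.na(trials$action), , drop = FALSE]
  ids <- params$subject_id
  beh <- t(vapply(ids, function(id) {
    x <- tr[tr$subject_id == id, , drop = FALSE]
    accs <- vapply(2:5, function(ss) {
      xs <- x[x$set_size == ss, , drop = FALSE]
      if (nrow(xs)) mean(xs$reward) else NA_real_
    }, numeric(1))
    rts <- vapply(2:5, function(ss) {
      xs <- x[x$set_size == ss & x$reward == 1, , drop = FALSE]
      if (nrow(xs)) mean(xs$rt) else NA_real_
    }, numeric(1))
    c(setNames(accs, paste0("acc_ss", 2:5)),
      acc_overall = mean(x$reward),
      setNames(rts, paste0("rt_correct_ss", 2:5)))
  }, numeric(9)))
  rownames(beh) <- ids
  if (anyNA(beh))
    stop("feature_tables: missing behavioral summaries (a subject with ",
         "no correct trials in some set size)")
  list(parameters = pm, behavior = beh)
}

ridge_fit <- function(X, y, lambda) {
  # X already standardized, y centered; intercept handled by centering
  p <- ncol(X)
  solve(crossprod(X) + diag(lambda, p), crossprod(X, y))
}

#' Repeated cross-validated ridge-regression evaluation
#'
#' For each repeat: an 80/20 train/test split stratified on the outcome
#' (continuous outcomes stratified by quantile bins), an inner k-fold
#' cross-validation over a log-spaced penalty grid on the training set
#' (features standardized and outcome centered within each training fold
#' only — no leakage), refit on the full training set at the selected
#' penalty, and evaluation on the held-out test set. Test MSE and
#' r-squared (`1 - SSE/SST`, can be negative) are aggregated over
#' repeats, along with the mean coefficient vector.
#'
#' @param features Numeric feature matrix (subjects x features).
#' @param target Numeric outcome vector.
#' @param n_repeats Number of split-CV-train-test repeats (default 100).
#' @param test_frac Held-out fraction (default 0.2).
#' @param k_folds Inner CV folds (default 10).
#' @param lambda_grid Penalty grid (default 13 log-spaced points in
#'   10^-3..10^3).
#' @param n_bins Quantile bins for stratifying a continuous outcome.
#' @param seed Integer seed.
#' @return Object of class `rlwm_prediction`: per-repeat metrics, their
#'   mean/SD/range, and mean coefficients with 95% intervals across
#'   repeats.
#' @export
repeated_ridge_eval <- function(features, target, n_repeats = 100L,
                                test_frac = 0.2, k_folds = 10L,
                                lambda_grid = 10^seq(-3, 3, length.out = 13),
                                n_bins = 5L, seed = 1L) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- as.numeric(target)
  n <- length(y)
  stopifnot(nrow(X) == n, n >= 30)
  bins <- cut(rank(y, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  if (any(table(bins) < 2))
    stop("repeated_ridge_eval: stratification bins too small")
  p <- ncol(X)
  mse <- numeric(n_repeats); r2 <- numeric(n_repeats)
  coefs <- matrix(NA_real_, n_repeats, p, dimnames = list(NULL, colnames(X)))
  lambdas <- numeric(n_repeats)
  with_seed(derive_seed(seed, 79L), {
    for (rep in seq_len(n_repeats)) {
      test <- unlist(lapply(split(seq_len(n), bins), function(ix) {
        k <- max(1L, round(test_frac * length(ix)))
        sample(ix, k)
      }), use.names = FALSE)
      train <- setdiff(seq_len(n), test)
      # inner CV over the penalty grid, within-fold standardization
      folds <- sample(rep_len(seq_len(k_folds), length(train)))
      cv_mse <- sapply(lambda_grid, function(lam) {
        errs <- vapply(seq_len(k_folds), function(f) {
          tr <- train[folds != f]; va <- train[folds == f]
          mu <- colMeans(X[tr, , drop = FALSE])
          sg <- apply(X[tr, , drop = FALSE], 2, sd)
          sg[sg == 0] <- 1
          Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
          Xva <- sweep(sweep(X[va, , drop = FALSE], 2, mu), 2, sg, "/")
          ym <- mean(y[tr])
          b <- ridge_fit(Xtr, y[tr] - ym, lam)
          mean((y[va] - (ym + Xva %*% b))^2)
        }, numeric(1))
        mean(errs)
      })
      lam <- lambda_grid[which.min(cv_mse)]
      lambdas[rep] <- lam
      mu <- colMeans(X[train, , drop = FALSE])
      sg <- apply(X[train, , drop = FALSE], 2, sd)
      sg[sg == 0] <- 1
      Xtr <- sweep(sweep(X[train, , drop = FALSE], 2, mu), 2, sg, "/")
      Xte <- sweep(sweep(X[test, , drop = FALSE], 2, mu), 2, sg, "/")
      ym <- mean(y[train])
      b <- ridge_fit(Xtr, y[train] - ym, lam)
      pred <- ym + Xte %*% b
      mse[rep] <- mean((y[test] - pred)^2)
      sst <- sum((y[test] - mean(y[test]))^2)
      r2[rep] <- 1 - sum((y[test] - pred)^2) / sst
      coefs[rep, ] <- b
    }
  })
  coef_mean <- colMeans(coefs)
  coef_ci <- apply(coefs, 2, quantile, c(0.025, 0.975))
  structure(list(
    per_repeat = data.frame(repeat_id = seq_len(n_repeats), mse = mse,
                            r2 = r2, lambda = lambdas),
    mse = c(mean = mean(mse), sd = sd(mse), min = min(mse), max = max(mse)),
    r2 = c(mean = mean(r2), sd = sd(r2), min = min(r2), max = max(r2)),
    coef_mean = coef_mean,
    coef_ci = coef_ci
  ), class = "rlwm_prediction")
}

#' @export
print.rlwm_prediction <- function(x, ...) {
  cat(sprintf("ridge prediction over %d repeats\n", nrow(x$per_repeat)))
  cat(sprintf("  MSE %.3f (SD %.3f, range [%.3f, %.3f])\n",
              x$mse["mean"], x$mse["sd"], x$mse["min"], x$mse["max"]))
  cat(sprintf("  r2  %.3f (SD %.3f, range [%.3f, %.3f])\n",
              x$r2["mean"], x$r2["sd"], x$r2["min"], x$r2["max"]))
  top <- names(sort(abs(x$coef_mean), decreasing = TRUE))[1]
  cat("  largest mean |coefficient|:", top, "\n")
  invisible(x)
}
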