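# Exposome -> BAG prediction under leakage-safe repeated nested CV.
# Standardization statistics, confound coefficients and hyperparameter
# choices are pure functions of the training fold; permutation significance
# reuses the cached per-fold feature pipeline (X never changes under a
# target shuffle) so each permutation only refits the learner.

#' Build the confound matrix
#'
#' The five covariates controlled for in the exposome stage: age, age
#' squared, sex, height, and volumetric scaling from the head image to
#' standard space.
#'
#' @param participants participant table with `age`, `sex`, `height`,
#'   `vol_scaling`.
#' @return numeric matrix with columns `age`, `age_sq`, `sex`, `height`,
#'   `vol_scaling` and `id` rownames.
#' @export
confound_matrix <- function(participants) {
  need <- c("age", "sex", "height", "vol_scaling")
  miss <- setdiff(need, names(participants))
  if (length(miss)) .stop_schema("missing confound column(s): ",
                                 paste(miss, collapse = ", "))
  out <- cbind(age = participants$age, age_sq = participants$age^2,
               sex = as.numeric(participants$sex),
               height = participants$height,
               vol_scaling = participants$vol_scaling)
  rownames(out) <- participants$id
  out
}

#' Residualize features on confounds with training-fold coefficients
#'
#' Per feature, an intercept-including linear confound model is fitted on
#' the training rows only; residuals for the apply rows are formed with
#' those train-fitted coefficients, so apply-row values can never influence
#' the fit.
#'
#' @param X feature matrix.
#' @param confounds confound matrix, rows aligned with `X`.
#' @param train_idx rows used to fit the confound models.
#' @param apply_idx rows to residualize (defaults to `train_idx`).
#' @return residualized matrix for `apply_idx` rows, with the fitted
#'   coefficient matrix in the `coefficients` attribute.
#' @export
remove_confounds <- function(X, confounds, train_idx,
                             apply_idx = train_idx) {
  X <- .assert_numeric_matrix(X)
  C <- .assert_numeric_matrix(confounds, "confounds")
  stopifnot(nrow(X) == nrow(C))
  Ct <- cbind(1, C[train_idx, , drop = FALSE])
  qrC <- qr(Ct)
  if (qrC$rank < ncol(Ct)) {
    stop("conditioning error: confound matrix is rank-deficient on the ",
         "training rows", call. = FALSE)
  }
  B <- qr.coef(qrC, X[train_idx, , drop = FALSE])
  res <- X[apply_idx, , drop = FALSE] -
    cbind(1, C[apply_idx, , drop = FALSE]) %*% B
  attr(res, "coefficients") <- B
  res
}

#' Cross-validation specification for BAG prediction
#'
#' @param outer_folds outer folds (default 5).
#' @param outer_repeats outer repeats (default 5).
#' @param inner_folds inner tuning folds (default 5).
#' @param algorithm `"random_forest"`, `"ridge"` or `"svr"`.
#' @param grid hyperparameter grid; `NULL` for [default_grid()].
#' @param seed integer seed for folds and stochastic fits.
#' @return an object of class `prediction_cv_spec`.
#' @export
prediction_cv_spec <- function(outer_folds = 5, outer_repeats = 5,
                               inner_folds = 5,
                               algorithm = c("random_forest", "ridge", "svr"),
                               grid = NULL, seed = 1) {
  algorithm <- match.arg(algorithm)
  stopifnot(outer_folds >= 2, outer_repeats >= 1, inner_folds >= 2)
  structure(list(outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds),
                 algorithm = algorithm, grid = grid, seed = as.integer(seed)),
            class = "prediction_cv_spec")
}

.fold_metrics <- function(y, pred) {
  err <- y - pred
  mse <- mean(err^2)
  c(mae = mean(abs(err)), mse = mse, rmse = sqrt(mse),
    r_squared = 1 - sum(err^2) / sum((y - mean(y))^2),
    pearson_r = if (sd(pred) > 0) cor(y, pred) else 0)
}

#' Predict BAG from exposome variables under repeated nested CV
#'
#' For every outer repeat and fold: standardize the features with
#' training-fold statistics, residualize them on the confounds with
#' train-fitted coefficients, tune hyperparameters on inner folds of the
#' training fold, fit, and predict the untouched test fold. Metrics (MAE,
#' MSE, RMSE, coefficient of determination, Pearson r) are computed per
#' fold and averaged; r is additionally pooled per repeat.
#'
#' @param X complete-case exposome matrix (post-curation).
#' @param y BAG target vector.
#' @param confounds confound matrix aligned with `X` rows (`NULL` to skip
#'   confound removal).
#' @param spec a [prediction_cv_spec()].
#' @param keep_fold_data keep the per-fold processed matrices and models
#'   (needed by [permutation_test()] and [explain_run()]).
#' @param row_ids optional unique row identifiers; when given, fold
#'   assignment is keyed on the sorted ids, making all results invariant to
#'   the row order of the input table.
#' @return an object of class `prediction_run`.
#' @export
run_prediction <- function(X, y, confounds = NULL,
                           spec = prediction_cv_spec(),
                           keep_fold_data = TRUE, row_ids = NULL) {
  X <- .assert_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(y) == n, n >= spec$outer_folds * 2)
  if (anyNA(X) || anyNA(y)) {
    stop("inputs must be complete cases (run the curation/subset steps first)",
         call. = FALSE)
  }
  if (sd(y) == 0) stop("degenerate target: constant y", call. = FALSE)
  if (!is.null(confounds)) {
    confounds <- .assert_numeric_matrix(confounds, "confounds")
    stopifnot(nrow(confounds) == n)
  }
  grid <- spec$grid %||% default_grid(spec$algorithm, ncol(X))
  if (!is.null(row_ids)) {
    stopifnot(length(row_ids) == n, !anyDuplicated(row_ids))
  }

  metrics <- list()
  repeats <- list()
  predictions <- matrix(NA_real_, n, spec$outer_repeats)
  for (r in seq_len(spec$outer_repeats)) {
    folds <- make_folds(n, spec$outer_folds,
                        seed = substream_seed(spec$seed, r))
    # fold membership keyed on sorted ids: row order cannot change results
    if (!is.null(row_ids)) folds <- folds[rank(row_ids)]
    fold_rec <- list()
    for (f in seq_len(spec$outer_folds)) {
      tr <- which(folds != f); te <- which(folds == f)
      sc <- .standardize_fit(X[tr, , drop = FALSE])
      Xs <- .standardize_apply(X, sc)
      if (!is.null(confounds)) {
        Xtr <- remove_confounds(Xs, confounds, tr, tr)
        coefs <- attr(Xtr, "coefficients")
        Xte <- remove_confounds(Xs, confounds, tr, te)
      } else {
        Xtr <- Xs[tr, , drop = FALSE]; Xte <- Xs[te, , drop = FALSE]
        coefs <- NULL
      }
      tuned <- tune_learner(Xtr, y[tr], spec$algorithm, grid,
                            k = spec$inner_folds,
                            seed = substream_seed(spec$seed, 1000 * r + f))
      model <- fit_learner(spec$algorithm, Xtr, y[tr], tuned$hyper,
                           seed = substream_seed(spec$seed, 1000 * r + f + 500))
      pred <- predict(model, Xte)
      predictions[te, r] <- pred
      metrics[[length(metrics) + 1]] <- data.frame(
        repeat_ = r, fold = f, t(.fold_metrics(y[te], pred)))
      fold_rec[[f]] <- list(
        test_idx = te, train_idx = tr, scaler = sc,
        confound_coef = coefs, hyper = tuned$hyper,
        model = if (keep_fold_data) model else NULL,
        Xtr = if (keep_fold_data) Xtr else NULL,
        Xte = if (keep_fold_data) Xte else NULL)
    }
    repeats[[r]] <- fold_rec
  }
  metrics <- do.call(rbind, metrics)
  met_names <- c("mae", "mse", "rmse", "r_squared", "pearson_r")
  summary <- colMeans(metrics[, met_names])
  pooled_r <- vapply(seq_len(spec$outer_repeats), function(r) {
    cor(y, predictions[, r])
  }, 0)
  structure(list(spec = spec, metrics = metrics, summary = summary,
                 pooled_r = mean(pooled_r), predictions = predictions,
                 y = y, n = n, folds = repeats,
                 xnames = colnames(X)),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("BAG prediction (%s), n = %d, %d x %d-fold CV\n",
              x$spec$algorithm, x$n, x$spec$outer_repeats,
              x$spec$outer_folds))
  cat(sprintf("  fold-mean: MAE %.3f, RMSE %.3f, R2 %.3f, Pearson r %.3f (pooled r %.3f)\n",
              s["mae"], s["rmse"], s["r_squared"], s["pearson_r"],
              x$pooled_r))
  if (!is.null(attr(x, "pvalues"))) {
    p <- attr(x, "pvalues")
    cat("  permutation p:", paste(sprintf("%s %.4g", names(p), p),
                                  collapse = ", "), "\n")
  }
  invisible(x)
}

#' Permutation significance of a prediction run
#'
#' Builds a per-metric null distribution by shuffling the target and
#' re-running the outer cross-validation (first repeat's fold structure;
#' the feature pipeline is cached because it does not depend on the
#' target). By default the tuned hyperparameters from the unpermuted run
#' are reused; `retune = TRUE` re-tunes inside every permutation. The
#' p-value is `(1 + b) / (1 + B)` where `b` counts permutations at least
#' as good as the observed value: `>=` for r-type metrics, `<=` for error
#' metrics. With `B` permutations the smallest attainable p is
#' `1 / (B + 1)`.
#'
#' @param run a [run_prediction()] result (with `keep_fold_data = TRUE`).
#' @param B number of permutations (default 500).
#' @param seed integer seed for the shuffles.
#' @param retune re-tune hyperparameters inside each permutation.
#' @return list with `p` (named vector over the five metrics), `q`
#'   (Benjamini-Hochberg adjusted across the metrics), `null` (B x 5
#'   matrix) and `observed`.
#' @export
permutation_test <- function(run, B = 500, seed = 1, retune = FALSE) {
  stopifnot(inherits(run, "prediction_run"), B >= 1)
  folds <- run$folds[[1]]
  if (is.null(folds[[1]]$Xtr)) {
    stop("run was built with `keep_fold_data = FALSE`", call. = FALSE)
  }
  y <- run$y
  met_names <- c("mae", "mse", "rmse", "r_squared", "pearson_r")
  null <- matrix(NA_real_, B, length(met_names),
                 dimnames = list(NULL, met_names))
  base_seed <- substream_seed(seed, 0)
  set.seed(base_seed)
  perms <- replicate(B, sample.int(run$n), simplify = FALSE)
  # per-fit seeds derived by cheap offset; only distinctness and
  # reproducibility matter here
  fit_seed <- function(b, f) (base_seed + 1009L * b + f) %% 2147483647L
  for (b in seq_len(B)) {
    yp <- y[perms[[b]]]
    fm <- matrix(NA_real_, length(folds), length(met_names))
    for (f in seq_along(folds)) {
      fr <- folds[[f]]
      hyper <- if (retune) {
        tune_learner(fr$Xtr, yp[fr$train_idx], run$spec$algorithm,
                     run$spec$grid %||%
                       default_grid(run$spec$algorithm, ncol(fr$Xtr)),
                     k = run$spec$inner_folds,
                     seed = fit_seed(b, f))$hyper
      } else {
        fr$hyper
      }
      m <- fit_learner(run$spec$algorithm, fr$Xtr, yp[fr$train_idx], hyper,
                       seed = fit_seed(b, f))
      fm[f, ] <- .fold_metrics(yp[fr$test_idx], predict(m, fr$Xte))
    }
    null[b, ] <- colMeans(fm)
  }
  observed <- run$summary[met_names]
  higher_better <- c(mae = FALSE, mse = FALSE, rmse = FALSE,
                     r_squared = TRUE, pearson_r = TRUE)
  p <- vapply(met_names, function(m) {
    b <- if (higher_better[m]) sum(null[, m] >= observed[m]) else
      sum(null[, m] <= observed[m])
    (1 + b) / (1 + B)
  }, 0)
  list(p = p, q = fdr_correct(p), null = null, observed = observed, B = B)
}

#' Smallest attainable permutation p-value
#'
#' Under the `(1 + b) / (1 + B)` estimator the minimum is `1 / (B + 1)`;
#' with the default 500 permutations this is 1/501, approximately 0.002.
#'
#' @param B number of permutations.
#' @return the p-value floor.
#' @export
permutation_p_floor <- function(B = 500) {
  stopifnot(B >= 1)
  1 / (B + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone in the p-value ranks, clipped at 1).
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted q-values in the original order.
#' @export
fdr_correct <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}
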