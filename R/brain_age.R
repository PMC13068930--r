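# Brain-age stage: select the healthy reference sample, train and tune
# age-regression candidates (algorithm x granularity), pick the best by
# held-out error, and apply the refitted model to new participants.

#' Cross-validation specification for brain-age training
#'
#' @param outer_folds outer folds for the nested CV estimate (default 10).
#' @param outer_repeats repeats of the outer loop (default 5).
#' @param inner_folds folds of the inner tuning loop (default 10).
#' @param holdout_fraction held-out fraction for model selection
#'   (default 0.2); the split is stratified by age decile.
#' @param seed integer seed controlling the split and all fold assignments.
#' @return an object of class `cv_spec`.
#' @export
cv_spec <- function(outer_folds = 10, outer_repeats = 5, inner_folds = 10,
                    holdout_fraction = 0.2, seed = 1) {
  stopifnot(outer_folds >= 2, outer_repeats >= 1, inner_folds >= 2,
            holdout_fraction > 0, holdout_fraction < 1)
  structure(list(outer_folds = as.integer(outer_folds),
                 outer_repeats = as.integer(outer_repeats),
                 inner_folds = as.integer(inner_folds),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "cv_spec")
}

#' Brain-age model candidate
#'
#' @param algorithm learner name (`"linear"`, `"ridge"`, `"svr"`,
#'   `"random_forest"`).
#' @param granularity region count of the grey-matter representation this
#'   candidate is trained on.
#' @param grid hyperparameter grid (data frame); `NULL` for
#'   [default_grid()], resolved at training time.
#' @return an object of class `model_candidate`.
#' @export
model_candidate <- function(algorithm, granularity, grid = NULL) {
  stopifnot(algorithm %in% c("linear", "ridge", "svr", "random_forest"))
  if (!is.null(grid) && nrow(grid) == 0 && algorithm != "linear") {
    stop("grid must be non-empty for tunable algorithms", call. = FALSE)
  }
  structure(list(algorithm = algorithm, granularity = as.integer(granularity),
                 grid = grid,
                 name = sprintf("%s_%d", algorithm, granularity)),
            class = "model_candidate")
}

#' Select the healthy reference sample
#'
#' Returns the ids of participants passing all health-eligibility criteria:
#' no long-standing illness, no diabetes, no stroke history, no diagnosed
#' condition, and good or excellent self-rated health (codes 1-2 on the
#' 1 = excellent .. 4 = poor scale).
#'
#' @param participants a participant table with the eligibility flag columns.
#' @return character vector of healthy participant ids.
#' @export
select_healthy <- function(participants) {
  need <- c("id", "long_standing_illness", "diabetes", "stroke",
            "icd10_diagnosis", "self_rated_health")
  miss <- setdiff(need, names(participants))
  if (length(miss)) {
    .stop_schema("participant table is missing flag column(s): ",
                 paste(miss, collapse = ", "))
  }
  ok <- !participants$long_standing_illness & !participants$diabetes &
    !participants$stroke & !participants$icd10_diagnosis &
    participants$self_rated_health <= 2
  participants$id[ok]
}

.standardize_fit <- function(X) {
  mu <- colMeans(X)
  sg <- apply(X, 2, sd)
  sg[sg == 0] <- 1
  list(mean = mu, sd = sg)
}
.standardize_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$mean, "-"), 2, sc$sd, "/")
}

#' Train and evaluate one brain-age candidate
#'
#' The healthy sample is split into a training fraction and an age-decile
#' stratified held-out fraction. Hyperparameters are chosen by inner
#' cross-validation on training rows only; a repeated outer loop yields
#' out-of-fold predictions and fold-wise metrics; the tuned model is then
#' fitted on the training fraction and evaluated once on the untouched
#' held-out rows. Features are standardized with training-fold statistics
#' throughout.
#'
#' @param features participants x regions matrix at the candidate's
#'   granularity.
#' @param ages chronological ages (years), aligned with `features` rows.
#' @param candidate a [model_candidate()].
#' @param cv a [cv_spec()].
#' @param refit if `TRUE` (default) also refit the tuned model on the full
#'   healthy sample (training + held-out) for downstream application.
#' @return an object of class `brainage_fit` with elements `candidate`,
#'   `evaluation` (held-out `mae`/`r`, fold-wise table, CV means), `model`
#'   (fitted on the training fraction), `full_model`, `split`, and `oof`
#'   (out-of-fold training-set predictions from the first outer repeat).
#' @export
train_candidate <- function(features, ages, candidate, cv = cv_spec(),
                            refit = TRUE) {
  X <- .assert_numeric_matrix(features, "features")
  stopifnot(nrow(X) == length(ages))
  if (anyNA(X)) stop("missing values in `features`", call. = FALSE)
  if (length(unique(ages)) < 2) {
    stop("degenerate target: fewer than 2 distinct ages", call. = FALSE)
  }
  grid <- candidate$grid %||% default_grid(candidate$algorithm, ncol(X))

  decile <- cut(ages, breaks = unique(quantile(ages, 0:10 / 10)),
                include.lowest = TRUE, labels = FALSE)
  sp <- holdout_split(nrow(X), cv$holdout_fraction,
                      seed = substream_seed(cv$seed, 0), strata = decile)
  tr <- sp$train; ho <- sp$holdout

  fit_fold <- function(rows_tr, rows_te, hyper, seed) {
    sc <- .standardize_fit(X[rows_tr, , drop = FALSE])
    m <- fit_learner(candidate$algorithm,
                     .standardize_apply(X[rows_tr, , drop = FALSE], sc),
                     ages[rows_tr], hyper, seed = seed)
    predict(m, .standardize_apply(X[rows_te, , drop = FALSE], sc))
  }

  ## outer CV on the training fraction ---------------------------------------
  per_fold <- list()
  oof <- rep(NA_real_, length(tr))
  for (r in seq_len(cv$outer_repeats)) {
    folds <- make_folds(length(tr), cv$outer_folds,
                        seed = substream_seed(cv$seed, 10 + r),
                        strata = decile[tr])
    for (f in seq_len(cv$outer_folds)) {
      i_tr <- tr[folds != f]; i_te <- tr[folds == f]
      sc_f <- .standardize_fit(X[i_tr, , drop = FALSE])
      tuned <- tune_learner(.standardize_apply(X[i_tr, , drop = FALSE], sc_f),
                            ages[i_tr],
                            candidate$algorithm, grid, k = cv$inner_folds,
                            seed = substream_seed(cv$seed, 100 * r + f))
      pr <- fit_fold(i_tr, i_te, tuned$hyper,
                     seed = substream_seed(cv$seed, 100 * r + f + 1))
      if (r == 1) oof[match(i_te, tr)] <- pr
      per_fold[[length(per_fold) + 1]] <- data.frame(
        repeat_ = r, fold = f, mae = mean(abs(ages[i_te] - pr)),
        r = if (sd(pr) > 0) cor(ages[i_te], pr) else 0)
    }
  }
  per_fold <- do.call(rbind, per_fold)

  ## tune on the full training fraction, evaluate on the held-out rows --------
  sc <- .standardize_fit(X[tr, , drop = FALSE])
  tuned <- tune_learner(.standardize_apply(X[tr, , drop = FALSE], sc),
                        ages[tr], candidate$algorithm,
                        grid, k = cv$inner_folds,
                        seed = substream_seed(cv$seed, 1))
  model <- fit_learner(candidate$algorithm,
                       .standardize_apply(X[tr, , drop = FALSE], sc),
                       ages[tr], tuned$hyper,
                       seed = substream_seed(cv$seed, 2))
  pred_ho <- predict(model, .standardize_apply(X[ho, , drop = FALSE], sc))
  evaluation <- list(
    holdout_mae = mean(abs(ages[ho] - pred_ho)),
    holdout_r = if (sd(pred_ho) > 0) cor(ages[ho], pred_ho) else 0,
    per_fold = per_fold,
    cv_mae = mean(per_fold$mae),
    cv_r = mean(tapply(per_fold$r, per_fold$repeat_, mean)))

  full_model <- NULL; sc_full <- NULL
  if (refit) {
    sc_full <- .standardize_fit(X)
    full_model <- fit_learner(candidate$algorithm,
                              .standardize_apply(X, sc_full), ages,
                              tuned$hyper, seed = substream_seed(cv$seed, 3))
  }
  structure(list(candidate = candidate, cv = cv, hyper = tuned$hyper,
                 evaluation = evaluation,
                 model = model, scaler = sc,
                 full_model = full_model, scaler_full = sc_full,
                 split = sp,
                 oof = data.frame(row = tr, age = ages[tr], predicted = oof),
                 holdout = data.frame(row = ho, age = ages[ho],
                                      predicted = pred_ho)),
            class = "brainage_fit")
}

#' Select the best brain-age candidate
#'
#' Minimal held-out MAE wins; ties are broken by higher held-out Pearson r,
#' then by lexicographic candidate name.
#'
#' @param fits list of [train_candidate()] results.
#' @return the winning `brainage_fit`.
#' @export
select_best_model <- function(fits) {
  if (length(fits) == 0) stop("empty candidate list", call. = FALSE)
  if (inherits(fits, "brainage_fit")) return(fits)
  mae <- vapply(fits, function(f) f$evaluation$holdout_mae, 0)
  r <- vapply(fits, function(f) f$evaluation$holdout_r, 0)
  nm <- vapply(fits, function(f) f$candidate$name, "")
  fits[[order(mae, -r, nm)[1]]]
}

#' Predict age from grey-matter features
#'
#' Applies a trained brain-age model (the full-sample refit when present,
#' otherwise the training-fraction model) to new rows. Feature columns are
#' checked against the training schema.
#'
#' @param fit a `brainage_fit`.
#' @param features matrix with the candidate's feature columns.
#' @return numeric vector of predicted ages (years), one per row.
#' @export
predict_age <- function(fit, features) {
  stopifnot(inherits(fit, "brainage_fit"))
  X <- .assert_numeric_matrix(features, "features")
  model <- fit$full_model %||% fit$model
  sc <- if (is.null(fit$full_model)) fit$scaler else fit$scaler_full
  if (!identical(colnames(X), model$xnames)) {
    if (!all(model$xnames %in% colnames(X))) {
      .stop_schema("feature mismatch: columns do not match the training schema")
    }
    X <- X[, model$xnames, drop = FALSE]
  }
  predict(model, .standardize_apply(X, sc))
}

#' @export
print.brainage_fit <- function(x, ...) {
  cat("Brain-age candidate", x$candidate$name, "\n")
  cat(sprintf("  held-out: MAE %.3f y, r %.3f (n = %d)\n",
              x$evaluation$holdout_mae, x$evaluation$holdout_r,
              nrow(x$holdout)))
  cat(sprintf("  outer CV: MAE %.3f y, r %.3f (%d x %d folds)\n",
              x$evaluation$cv_mae, x$evaluation$cv_r,
              x$cv$outer_repeats, x$cv$outer_folds))
  invisible(x)
}
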