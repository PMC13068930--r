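test_that("healthy selection applies every eligibility flag", {
  parts <- data.frame(
    id = paste0("P", 1:6),
    long_standing_illness = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    diabetes = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stroke = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    icd10_diagnosis = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    self_rated_health = c(1, 1, 2, 1, 2, 3))
  expect_identical(select_healthy(parts), "P1")
  parts_all_ok <- parts
  parts_all_ok[2:6, 2:5] <- FALSE
  parts_all_ok$self_rated_health <- 2
  expect_identical(select_healthy(parts_all_ok), parts$id)
  expect_error(select_healthy(parts[, -3]), "missing flag")

  # flags are deterministic: flagged fraction matches the configuration exactly
  b <- generate_cohort(small_config(n = 500, seed = 3))
  frac <- length(select_healthy(b$participants)) / 500
  expect_equal(frac, 1 - round(0.2 * 500) / 500, tolerance = 1e-12)
})

test_that("ridge recovers age on a noise-free cohort and fails on shuffled ages", {
  cfg <- cohort_config(n_participants = 300, n_regions = 20,
                       granularity_levels = 20, noise_sd_gm = 0,
                       deviation_sd = 0, nonhealthy_fraction = 0, seed = 2)
  b <- generate_cohort(cfg, null_effects())
  X <- b$gm[["20"]]
  ages <- b$participants$age
  cand <- model_candidate("ridge", 20, grid = data.frame(lambda = c(1e-4, 1e-2)))
  cv <- cv_spec(outer_folds = 3, outer_repeats = 1, inner_folds = 3,
                holdout_fraction = 0.2, seed = 4)
  fit <- train_candidate(X, ages, cand, cv)
  expect_lt(fit$evaluation$holdout_mae, 0.5)
  # memorization limit: training rows are reproduced up to regularization bias
  pred_tr <- predict(fit$model,
                     expobag:::.standardize_apply(X[fit$split$train, ], fit$scaler))
  expect_lt(mean(abs(pred_tr - ages[fit$split$train])), 0.5)

  set.seed(9)
  fit_null <- train_candidate(X, sample(ages), cand, cv)
  expect_lt(abs(fit_null$evaluation$holdout_r), 0.25)

  expect_error(train_candidate(X, rep(60, nrow(X)), cand, cv), "degenerate")
})

test_that("holdout rows never enter tuning and schema mismatches are caught", {
  b <- generate_cohort(small_config(n = 200, seed = 6), null_effects())
  X <- b$gm[["20"]]
  cand <- model_candidate("ridge", 20, grid = data.frame(lambda = 1))
  fit <- train_candidate(X, b$participants$age, cand,
                         cv_spec(3, 1, 3, 0.25, seed = 1))
  expect_length(intersect(fit$split$train, fit$split$holdout), 0)
  expect_setequal(c(fit$split$train, fit$split$holdout), seq_len(nrow(X)))
  # out-of-fold predictions exist for every training row
  expect_false(anyNA(fit$oof$predicted))
  # a candidate fitted without the right columns refuses to predict
  Xbad <- X[, 1:10]
  expect_error(predict_age(fit, Xbad), "feature mismatch")
  # constant feature rows give constant predictions
  Xc <- X[rep(1, 5), ]
  expect_equal(diff(range(predict_age(fit, Xc))), 0, tolerance = 1e-10)
})

test_that("model selection takes the minimum held-out MAE with documented tie-breaks", {
  mk <- function(name, mae, r) {
    structure(list(candidate = list(name = name),
                   evaluation = list(holdout_mae = mae, holdout_r = r)),
              class = "fake_fit")
  }
  one <- mk("a_100", 4.2, 0.7)
  expect_identical(select_best_model(list(one))$candidate$name, "a_100")
  got <- select_best_model(list(mk("a_100", 4.2, 0.7), mk("b_100", 3.9, 0.6)))
  expect_identical(got$candidate$name, "b_100")
  # MAE tie: higher r wins
  got <- select_best_model(list(mk("a_100", 3.9, 0.6), mk("b_100", 3.9, 0.8)))
  expect_identical(got$candidate$name, "b_100")
  # full tie: lexicographic name
  got <- select_best_model(list(mk("z_100", 3.9, 0.6), mk("b_100", 3.9, 0.6)))
  expect_identical(got$candidate$name, "b_100")
  expect_error(select_best_model(list()), "empty")
})

test_that("the granularity carrying the signal is selected across seeds", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    n <- 240
    ages <- runif(n, 44, 82)
    Xsig <- matrix(rnorm(n * 12), n, 12) + outer(ages, rep(1, 12))
    colnames(Xsig) <- paste0("s", 1:12)
    Xnoise <- matrix(rnorm(n * 6), n, 6)
    colnames(Xnoise) <- paste0("q", 1:6)
    cv <- cv_spec(3, 1, 3, 0.25, seed = s)
    grid <- data.frame(lambda = 0.01)
    f_sig <- train_candidate(Xsig, ages, model_candidate("ridge", 12, grid), cv)
    f_noise <- train_candidate(Xnoise, ages, model_candidate("ridge", 6, grid), cv)
    best <- select_best_model(list(f_sig, f_noise))
    if (best$candidate$granularity == 12) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
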