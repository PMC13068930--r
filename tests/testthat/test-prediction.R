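test_that("confound residualization is fitted on training rows only", {
  set.seed(1)
  n <- 2000
  C <- cbind(age = runif(n, 44, 82), sex = rbinom(n, 1, 0.5))
  X <- cbind(same = C[, "age"],                      # identical to a confound
             ortho = rnorm(n))                       # independent of confounds
  tr <- 1:1000; ap <- 1001:2000
  res_tr <- remove_confounds(X, C, tr)
  expect_lt(max(abs(res_tr[, "same"])), 1e-8)
  res_ap <- remove_confounds(X, C, tr, ap)
  expect_gt(cor(res_ap[, "ortho"], X[ap, "ortho"]), 0.99)

  # tampering with apply rows never changes the fitted coefficients
  X2 <- X; X2[ap, ] <- X2[ap, ] * 100 + 7
  expect_identical(attr(remove_confounds(X2, C, tr, ap), "coefficients"),
                   attr(res_ap, "coefficients"))

  expect_error(remove_confounds(X, cbind(C, C[, 1]), tr), "rank-deficient")
})

test_that("nested CV recovers a noiseless linear signal and reports a null for independent targets", {
  set.seed(2)
  n <- 400
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  spec <- prediction_cv_spec(5, 1, 3, "ridge",
                             grid = data.frame(lambda = 1e-4), seed = 3)
  run <- run_prediction(X, 2 * X[, 1], NULL, spec)
  expect_gt(run$summary["pearson_r"], 0.99)
  # rmse^2 equals mse in every fold, and rmse is non-negative
  expect_equal(run$metrics$rmse^2, run$metrics$mse, tolerance = 1e-12)
  expect_true(all(run$metrics$rmse >= 0))

  set.seed(3)
  run0 <- run_prediction(X, rnorm(n), NULL, spec)
  expect_lt(abs(run0$summary["pearson_r"]), 0.15)

  expect_error(run_prediction(X, rep(1, n), NULL, spec), "constant y")
  expect_error(run_prediction(X[1:6, ], rnorm(6), NULL, spec), "outer_folds")
})

test_that("results are invariant to the row order of the input table", {
  set.seed(4)
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- X[, 1] + rnorm(n, 0, 0.5)
  C <- cbind(age = runif(n, 44, 82))
  ids <- sprintf("id%03d", sample(n))
  spec <- prediction_cv_spec(4, 1, 3, "ridge",
                             grid = data.frame(lambda = 1), seed = 5)
  r1 <- run_prediction(X, y, C, spec, row_ids = ids)
  perm <- sample(n)
  r2 <- run_prediction(X[perm, ], y[perm], C[perm, , drop = FALSE], spec,
                       row_ids = ids[perm])
  expect_equal(r1$summary, r2$summary, tolerance = 1e-12)
  p1 <- r1$predictions[, 1]; names(p1) <- ids
  p2 <- r2$predictions[, 1]; names(p2) <- ids[perm]
  expect_equal(p1[sort(ids)], p2[sort(ids)], tolerance = 1e-12)
})

test_that("permutation p-values respect the (1+b)/(1+B) floor and are deterministic", {
  set.seed(5)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 3 * X[, 2] + rnorm(n, 0, 0.3)
  spec <- prediction_cv_spec(5, 1, 3, "ridge",
                             grid = data.frame(lambda = 1e-3), seed = 6)
  run <- run_prediction(X, y, NULL, spec)
  pt <- permutation_test(run, B = 20, seed = 9)
  # strong signal beats every null: the floor is attained for r-type metrics
  expect_equal(unname(pt$p["pearson_r"]), 1 / 21, tolerance = 1e-12)
  expect_equal(unname(pt$p["mae"]), 1 / 21, tolerance = 1e-12)
  expect_true(all(pt$p >= 1 / 21 & pt$p <= 1))
  pt2 <- permutation_test(run, B = 20, seed = 9)
  expect_identical(pt$null, pt2$null)
  expect_identical(dim(pt$null), c(20L, 5L))

  expect_equal(permutation_p_floor(500), 1 / 501, tolerance = 1e-15)
})

test_that("fold artifacts are pure functions of training rows (tamper audit)", {
  set.seed(6)
  n <- 240
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- X[, 1] - X[, 3] + rnorm(n, 0, 0.5)
  C <- cbind(age = runif(n, 44, 82), sex = rbinom(n, 1, 0.5))
  spec <- prediction_cv_spec(4, 1, 3, "random_forest",
                             grid = expand.grid(mtry = c(2, 4),
                                                min.node.size = 10,
                                                num.trees = 30),
                             seed = 7)
  base <- run_prediction(X, y, C, spec)
  for (f in seq_along(base$folds[[1]])) {
    te <- base$folds[[1]][[f]]$test_idx
    X2 <- X; X2[te, ] <- matrix(rnorm(length(te) * 6, 50, 10), length(te), 6)
    y2 <- y; y2[te] <- y2[te] + 100
    C2 <- C; C2[te, ] <- C2[te, ] + 5
    tampered <- run_prediction(X2, y2, C2, spec)
    expect_identical(tampered$folds[[1]][[f]]$scaler,
                     base$folds[[1]][[f]]$scaler)
    expect_identical(tampered$folds[[1]][[f]]$confound_coef,
                     base$folds[[1]][[f]]$confound_coef)
    expect_identical(tampered$folds[[1]][[f]]$hyper,
                     base$folds[[1]][[f]]$hyper)
  }
})

test_that("BH adjustment matches the hand step-up and validates its input", {
  expect_equal(fdr_correct(0.03), 0.03, tolerance = 1e-15)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_correct(c(0.5, NA)), "\\[0, 1\\]")
})
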