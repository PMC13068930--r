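test_that("tree attributions match the brute-force Shapley oracle per tree", {
  set.seed(1)
  n <- 150; p <- 4
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- X[, 1] * 2 + X[, 2] * X[, 3] + rnorm(n, 0, 0.3)
  model <- fit_learner("random_forest", X, y,
                       list(num.trees = 6, min.node.size = 15, mtry = 2),
                       seed = 2)
  Xex <- X[1:4, , drop = FALSE]
  at <- compute_attributions(model, Xex, X, method = "tree")
  phi_oracle <- matrix(0, nrow(Xex), p)
  for (k in 1:6) {
    tr <- ranger_tree_arrays(model$fit, k, X)
    for (i in seq_len(nrow(Xex))) {
      phi_oracle[i, ] <- phi_oracle[i, ] + brute_tree_shap(tr, Xex[i, ], p)
    }
  }
  phi_oracle <- phi_oracle / 6
  expect_equal(unname(at$values), phi_oracle, tolerance = 1e-10)
})

test_that("local accuracy holds for every method and violations are caught", {
  set.seed(3)
  n <- 120; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- X[, 1] - 0.5 * X[, 4] + rnorm(n, 0, 0.2)
  Xex <- X[1:10, , drop = FALSE]
  for (setup in list(list("random_forest", list(num.trees = 20,
                                                min.node.size = 10)),
                     list("ridge", list(lambda = 0.1)),
                     list("linear", list()),
                     list("svr", list(cost = 1)))) {
    model <- fit_learner(setup[[1]], X, y, setup[[2]], seed = 4)
    bg <- if (setup[[1]] == "random_forest") X else X[1:40, , drop = FALSE]
    at <- compute_attributions(model, Xex, bg, nsim = 8, seed = 5)
    gap <- max(abs(at$base_value + rowSums(at$values) - at$predictions))
    expect_lt(gap, 1e-6 * max(1, sd(at$predictions)))
  }
  # a background that misses tree nodes is rejected, not silently wrong
  model_rf <- fit_learner("random_forest", X, y,
                          list(num.trees = 20, min.node.size = 10), seed = 4)
  expect_error(compute_attributions(model_rf, Xex, X[1:5, , drop = FALSE]),
               "background")
  # an inconsistent result is rejected: impossible tolerance forces the error
  model <- fit_learner("svr", X, y, list(cost = 1), seed = 4)
  expect_error(
    compute_attributions(model, Xex, X, nsim = 2, tolerance = 1e-300),
    "local-accuracy")
})

test_that("linear attributions equal beta_j * (x_ij - mean_j) for independent features", {
  set.seed(6)
  n <- 300; p <- 4
  X <- scale(matrix(rnorm(n * p), n, p))
  colnames(X) <- paste0("v", 1:p)
  beta <- c(2, -1, 0.5, 0)
  y <- as.numeric(X %*% beta) + rnorm(n, 0, 0.1)
  model <- fit_learner("linear", X, y)
  at <- compute_attributions(model, X[1:20, ], X)
  bhat <- model$fit$coef[-1]
  expected <- sweep(sweep(X[1:20, ], 2, colMeans(X), "-"), 2, bhat, "*")
  expect_equal(unname(at$values), unname(expected), tolerance = 1e-6)
})

test_that("a constant model attributes nothing", {
  model <- structure(list(algorithm = "linear", hyper = list(),
                          fit = list(coef = c(5, 0, 0, 0)),
                          xnames = paste0("v", 1:3), seed = 1),
                     class = "expobag_learner")
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("v", 1:3)))
  at <- compute_attributions(model, X, X)
  expect_true(all(at$values == 0))
  expect_equal(at$base_value, 5, tolerance = 1e-12)
})

test_that("contribution ranking orders by mean |attribution| with name tie-breaks", {
  set.seed(7)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("v", 1:6)))
  y <- 3 * X[, 2] + 0.5 * X[, 5] + rnorm(n, 0, 0.2)
  model <- fit_learner("linear", X, y)
  at <- compute_attributions(model, X, X)
  rk <- rank_contributions(at)
  expect_identical(rk$variable[1], "v2")
  expect_identical(rk$rank, 1:6)
  expect_identical(nrow(rank_contributions(at, top_k = 3)), 3L)
  # dominant effect pushes the prediction in its own direction
  expect_gt(rk$sign_assoc[1], 0.9)

  # exact ties are broken by variable name
  at2 <- at
  at2$values <- matrix(1, 4, 3, dimnames = list(NULL, c("b", "c", "a")))
  at2$X <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("b", "c", "a")))
  expect_identical(rank_contributions(at2)$variable, c("a", "b", "c"))
})

test_that("fold stability is 1 for identical folds and near 0 for independent rankings", {
  mk_attr <- function(vals) {
    structure(list(values = vals, base_value = 0,
                   predictions = rowSums(vals), X = vals, meta = NULL),
              class = "attribution")
  }
  v <- matrix(abs(rnorm(200)), 10, 20, dimnames = list(NULL, paste0("v", 1:20)))
  expect_equal(fold_stability(list(mk_attr(v), mk_attr(v))), 1,
               tolerance = 1e-12)
  set.seed(8)
  indep <- lapply(1:5, function(i) {
    mk_attr(matrix(abs(rnorm(50 * 30)), 30, 50,
                   dimnames = list(NULL, paste0("v", 1:50))))
  })
  expect_lt(abs(fold_stability(indep)), 0.2)
  expect_error(fold_stability(list(mk_attr(v))), "at least 2")
})

test_that("univariate associations recover identity and planted effect sizes", {
  set.seed(9)
  # a variable equal to the outcome has r = 1 and standardized beta 1
  yb <- rnorm(200)
  X1 <- cbind(same = yb)
  ua <- univariate_association(X1, yb)
  expect_equal(ua$r_marginal, 1, tolerance = 1e-12)
  expect_equal(ua$beta_std, 1, tolerance = 1e-10)

  # planted linear effects: standardized beta close to strength / sd(d)
  b <- generate_cohort(cohort_config(n_participants = 3000, n_regions = 4,
                                     granularity_levels = 4, seed = 10))
  gt <- b$ground_truth
  X <- as.matrix(b$exposome[, c("exp_linear_1", "exp_linear_2")])
  ua2 <- univariate_association(X, gt$d)
  strengths <- vapply(gt$effects[c("exp_linear_1", "exp_linear_2")],
                      `[[`, 0, "strength")
  implied <- strengths / sd(gt$d)
  se <- 2 / sqrt(3000)
  expect_lt(max(abs(ua2$beta_std - implied)), 2 * se + 0.02)
})

test_that("explaining a run covers every test fold exactly once with fold provenance", {
  set.seed(11)
  n <- 200
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  y <- 2 * X[, 1] + rnorm(n, 0, 0.4)
  spec <- prediction_cv_spec(4, 1, 3, "random_forest",
                             grid = expand.grid(mtry = 2, min.node.size = 10,
                                                num.trees = 30),
                             seed = 12)
  run <- run_prediction(X, y, NULL, spec)
  at <- explain_run(run, repeats = 1)
  expect_identical(sort(at$meta$row), 1:n)
  expect_identical(nrow(at$values), as.integer(n))
  rk <- rank_contributions(at)
  expect_identical(rk$variable[1], "v1")
  expect_gte(fold_stability(at), -1)
})
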