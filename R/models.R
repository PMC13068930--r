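# Learner wrappers: one thin, uniform interface over the four regression
# algorithms used by both prediction stages. Matrices in, numeric predictions
# out; every stochastic fit takes an explicit seed.

#' Fit a regression learner
#'
#' @param algorithm one of `"linear"`, `"ridge"`, `"svr"`, `"random_forest"`.
#' @param X numeric feature matrix (column names are the training schema).
#' @param y numeric target.
#' @param hyper named list of hyperparameters; see [default_grid()] for the
#'   tunable set of each algorithm.
#' @param seed integer seed for stochastic learners (random forest).
#' @return an object of class `expobag_learner`.
#' @export
fit_learner <- function(algorithm = c("linear", "ridge", "svr", "random_forest"),
                        X, y, hyper = list(), seed = 1) {
  algorithm <- match.arg(algorithm)
  X <- .assert_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2) {
    stop("degenerate target: fewer than 2 distinct values in `y`", call. = FALSE)
  }
  fit <- switch(algorithm,
    linear = {
      f <- lm.fit(cbind(`(Intercept)` = 1, X), y)
      list(coef = ifelse(is.na(f$coefficients), 0, f$coefficients))
    },
    ridge = {
      lambda <- hyper$lambda %||% 1
      glmnet::glmnet(X, y, alpha = 0, lambda = lambda,
                     standardize = FALSE, intercept = TRUE)
    },
    svr = {
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = hyper$cost %||% 1,
                 gamma = hyper$gamma %||% (1 / ncol(X)),
                 epsilon = hyper$epsilon %||% 0.1, scale = FALSE)
    },
    random_forest = {
      d <- data.frame(.y = y, X, check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".y", data = d,
        num.trees = hyper$num.trees %||% 100,
        mtry = hyper$mtry %||% max(1L, floor(sqrt(ncol(X)))),
        min.node.size = hyper$min.node.size %||% 20,
        max.depth = hyper$max.depth %||% 0,
        num.threads = 1, seed = seed, respect.unordered.factors = FALSE)
    })
  structure(list(algorithm = algorithm, hyper = hyper, fit = fit,
                 xnames = colnames(X), seed = seed),
            class = "expobag_learner")
}

#' Predict from a fitted learner
#'
#' @param object an `expobag_learner`.
#' @param X feature matrix whose columns match the training schema.
#' @param ... unused.
#' @return numeric vector of predictions, one per row.
#' @export
predict.expobag_learner <- function(object, X, ...) {
  X <- .assert_numeric_matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!identical(colnames(X), object$xnames)) {
    if (!all(object$xnames %in% colnames(X))) {
      .stop_schema("feature mismatch: prediction matrix does not contain the ",
                   "training columns")
    }
    X <- X[, object$xnames, drop = FALSE]
  }
  out <- switch(object$algorithm,
    linear = as.numeric(cbind(1, X) %*% object$fit$coef),
    ridge = {
      lam <- object$hyper$lambda %||% 1
      if (length(object$fit$lambda) == 1) {
        # single-penalty fit: read the coefficients off the slots directly
        # (predict.glmnet's S4 dispatch dominates at small problem sizes)
        as.numeric(X %*% object$fit$beta[, 1]) + object$fit$a0[[1]]
      } else {
        as.numeric(predict(object$fit, newx = X, s = lam))
      }
    },
    svr = as.numeric(predict(object$fit, newdata = X)),
    random_forest = {
      d <- data.frame(X, check.names = FALSE)
      as.numeric(predict(object$fit, data = d, num.threads = 1)$predictions)
    })
  if (any(!is.finite(out))) stop("non-finite predictions", call. = FALSE)
  out
}

#' Default hyperparameter grids
#'
#' Small desk-scale grids: ridge penalties on a log grid, compact
#' cost/width grids for SVR, and mtry/node-size grids for random forest.
#' The linear learner has no tunable parameters.
#'
#' @param algorithm learner name.
#' @param p number of features (used to scale mtry and the kernel width).
#' @return a data frame with one row per hyperparameter combination.
#' @export
default_grid <- function(algorithm, p) {
  switch(algorithm,
    linear = data.frame(row.names = "1"),
    ridge = data.frame(lambda = 10^seq(-3, 3, by = 2)),
    svr = expand.grid(cost = c(1, 10), gamma = c(0.5, 2) / p, epsilon = 0.1),
    random_forest = expand.grid(
      mtry = unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3)))),
      min.node.size = c(10, 30), num.trees = 100),
    stop("unknown algorithm: ", algorithm, call. = FALSE))
}

#' Tune a learner by inner cross-validation
#'
#' Selects the grid row with minimal cross-validated mean squared error on
#' `X`/`y` alone; callers pass training-fold rows only, so the choice is a
#' pure function of the training fold.
#'
#' @param X,y training features and target.
#' @param algorithm learner name.
#' @param grid data frame of candidate hyperparameters (one combination per
#'   row); `NULL` for [default_grid()].
#' @param k number of inner folds.
#' @param seed seed controlling inner fold assignment and stochastic fits.
#' @return list with `hyper` (the chosen row as a list) and `cv_mse`.
#' @export
tune_learner <- function(X, y, algorithm, grid = NULL, k = 5, seed = 1) {
  X <- .assert_numeric_matrix(X)
  if (is.null(grid)) grid <- default_grid(algorithm, ncol(X))
  if (nrow(grid) <= 1) {
    hy <- if (nrow(grid) == 1) as.list(grid[1, , drop = FALSE]) else list()
    return(list(hyper = hy, cv_mse = NA_real_))
  }
  folds <- make_folds(nrow(X), k, seed = substream_seed(seed, 0))
  mse <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    hy <- as.list(grid[g, , drop = FALSE])
    err <- 0
    for (f in seq_len(k)) {
      tr <- which(folds != f); te <- which(folds == f)
      m <- fit_learner(algorithm, X[tr, , drop = FALSE], y[tr], hy,
                       seed = substream_seed(seed, f))
      err <- err + sum((y[te] - predict(m, X[te, , drop = FALSE]))^2)
    }
    mse[g] <- err / nrow(X)
  }
  best <- which.min(mse)
  list(hyper = as.list(grid[best, , drop = FALSE]), cv_mse = mse[best])
}
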