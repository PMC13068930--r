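# Shapley additive attributions. Tree ensembles use the exact
# path-dependent polynomial-time algorithm (compiled, src/treeshap.cpp)
# with node covers from the training-fold background; linear models use
# the closed form; other models use a permutation-sampling estimator whose
# telescoping sum makes local accuracy exact regardless of the budget.

.extract_forest <- function(fit, background) {
  ntree <- fit$num.trees
  lapply(seq_len(ntree), function(k) {
    ti <- ranger::treeInfo(fit, k)
    leaf <- ti$terminal
    tr <- list(left = ifelse(leaf, -1L, as.integer(ti$leftChild)),
               right = ifelse(leaf, -1L, as.integer(ti$rightChild)),
               feature = ifelse(leaf, 0L, as.integer(ti$splitvarID)),
               threshold = ifelse(leaf, 0, ti$splitval),
               value = ifelse(leaf, ti$prediction, 0))
    st <- .tree_node_stats(tr$left, tr$right, tr$feature, tr$threshold,
                           background, numeric(nrow(background)))
    if (any(st$cover == 0)) {
      stop("background does not reach every tree node; use the model's ",
           "training data (or a superset) as the background", call. = FALSE)
    }
    tr$cover <- st$cover
    tr
  })
}

.shap_linear <- function(learner, X, background) {
  beta <- switch(learner$algorithm,
    linear = learner$fit$coef,
    ridge = {
      cf <- as.numeric(coef(learner$fit, s = learner$hyper$lambda %||% 1))
      names(cf) <- c("(Intercept)", learner$xnames)
      cf
    })
  b <- beta[-1]
  mu <- colMeans(background)
  phi <- sweep(sweep(X, 2, mu, "-"), 2, b, "*")
  colnames(phi) <- colnames(X)
  list(phi = phi, base_value = unname(beta[1] + sum(b * mu)))
}

.shap_sampling <- function(learner, X, background, nsim, seed) {
  set.seed(seed)
  n <- nrow(X); p <- ncol(X); nb <- nrow(background)
  phi <- matrix(0, n, p, dimnames = list(NULL, colnames(X)))
  base <- mean(predict(learner, background))
  for (i in seq_len(n)) {
    x <- X[i, ]
    acc <- numeric(p)
    for (s in seq_len(nsim)) {
      ord <- sample.int(p)
      # telescoping chain: start from the background, switch features to x
      # one at a time in permutation order; each step's change in the mean
      # prediction is that feature's contribution for this permutation
      Z <- background
      v_prev <- base
      for (j in ord) {
        Z[, j] <- x[j]
        v <- mean(predict(learner, Z))
        acc[j] <- acc[j] + (v - v_prev)
        v_prev <- v
      }
    }
    phi[i, ] <- acc / nsim
  }
  list(phi = phi, base_value = base)
}

#' Shapley attributions for a fitted learner
#'
#' Additive per-sample per-variable contributions satisfying the local
#' accuracy identity: base value plus the row sum of attributions equals
#' the model prediction. Tree ensembles are explained exactly with the
#' path-dependent tree algorithm (node covers taken from `background`,
#' normally the training fold); linear and ridge models with the closed
#' form `beta_j * (x_ij - mean_j)`; any other model with a
#' permutation-sampling estimator of `nsim` permutations against the
#' background set.
#'
#' @param model an `expobag_learner`.
#' @param X rows to explain (matching the training schema; for models
#'   trained inside [run_prediction()] this is the processed test fold).
#' @param background reference matrix (training-fold features).
#' @param method `"auto"` (by algorithm), `"tree"`, `"linear"` or
#'   `"sampling"`.
#' @param nsim permutations for the sampling estimator.
#' @param tolerance maximum allowed |base + sum(phi) - prediction|;
#'   defaults to `1e-6 * max(1, sd(prediction))`. Violations raise a
#'   consistency error with diagnostics.
#' @param seed seed for the sampling estimator.
#' @return an object of class `attribution`: list with `values` (n x p
#'   matrix), `base_value`, `predictions`, `X`, `method`.
#' @export
compute_attributions <- function(model, X, background,
                                 method = c("auto", "tree", "linear",
                                            "sampling"),
                                 nsim = 64, tolerance = NULL, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "expobag_learner"))
  X <- .assert_numeric_matrix(X)
  background <- .assert_numeric_matrix(background, "background")
  if (is.null(colnames(X))) colnames(X) <- model$xnames
  if (method == "auto") {
    method <- switch(model$algorithm,
      random_forest = "tree", linear = "linear", ridge = "linear",
      "sampling")
  }
  res <- switch(method,
    tree = {
      stopifnot(model$algorithm == "random_forest")
      trees <- .extract_forest(model$fit, background)
      out <- .treeshap_forest(trees, X)
      colnames(out$phi) <- colnames(X)
      out
    },
    linear = .shap_linear(model, X, background),
    sampling = .shap_sampling(model, X, background, nsim, seed))
  pred <- predict(model, X)
  recon <- res$base_value + rowSums(res$phi)
  tol <- tolerance %||% (1e-6 * max(1, sd(pred)))
  gap <- max(abs(recon - pred))
  if (gap > tol) {
    stop(sprintf(paste0("local-accuracy violation: max |base + sum(phi) - ",
                        "prediction| = %.3g > tolerance %.3g (method %s, ",
                        "n = %d, p = %d)"),
                 gap, tol, method, nrow(X), ncol(X)), call. = FALSE)
  }
  structure(list(values = res$phi, base_value = res$base_value,
                 predictions = pred, X = X, method = method,
                 meta = NULL),
            class = "attribution")
}

#' Explain a prediction run on its held-out folds
#'
#' Computes attributions for every outer test fold with the fold's own
#' model and training-fold background, and concatenates them with
#' fold/repeat provenance. Samples are explained only by models that never
#' saw them.
#'
#' @param run a [run_prediction()] result (with `keep_fold_data = TRUE`).
#' @param repeats outer repeats to explain (default 1, the first).
#' @param ... passed to [compute_attributions()].
#' @return an `attribution` object whose `meta` data frame carries
#'   `repeat_`, `fold` and `row` (original row index) per explained sample.
#' @export
explain_run <- function(run, repeats = 1, ...) {
  stopifnot(inherits(run, "prediction_run"))
  vals <- list(); meta <- list(); preds <- list(); base <- list(); xs <- list()
  for (r in repeats) {
    folds <- run$folds[[r]]
    if (is.null(folds[[1]]$model)) {
      stop("run was built with `keep_fold_data = FALSE`", call. = FALSE)
    }
    for (f in seq_along(folds)) {
      fr <- folds[[f]]
      at <- compute_attributions(fr$model, fr$Xte, fr$Xtr, ...)
      vals[[length(vals) + 1]] <- at$values
      preds[[length(preds) + 1]] <- at$predictions
      base[[length(base) + 1]] <- rep(at$base_value, nrow(fr$Xte))
      xs[[length(xs) + 1]] <- fr$Xte
      meta[[length(meta) + 1]] <- data.frame(
        repeat_ = r, fold = f, row = fr$test_idx)
    }
  }
  structure(list(values = do.call(rbind, vals),
                 base_value = unlist(base),
                 predictions = unlist(preds),
                 X = do.call(rbind, xs),
                 method = NULL,
                 meta = do.call(rbind, meta)),
            class = "attribution")
}

#' Rank variables by mean absolute attribution
#'
#' @param attr an `attribution` object.
#' @param top_k number of rows to return (default: all).
#' @return data frame with `variable`, `mean_abs_attr`, `rank` (ties broken
#'   by variable name) and `sign_assoc`, the correlation between a
#'   variable's attribution and its value (positive: higher values push the
#'   prediction up).
#' @export
rank_contributions <- function(attr, top_k = NULL) {
  stopifnot(inherits(attr, "attribution"), nrow(attr$values) > 0)
  mam <- colMeans(abs(attr$values))
  sign_assoc <- vapply(seq_along(mam), function(j) {
    v <- attr$values[, j]; x <- attr$X[, j]
    if (sd(v) == 0 || sd(x) == 0) 0 else cor(x, v)
  }, 0)
  ord <- order(-mam, names(mam))
  out <- data.frame(variable = names(mam)[ord],
                    mean_abs_attr = unname(mam[ord]),
                    rank = seq_along(mam),
                    sign_assoc = unname(sign_assoc[ord]))
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' Cross-fold stability of the attribution ranking
#'
#' Mean pairwise Spearman rank correlation of per-fold mean absolute
#' attribution profiles.
#'
#' @param attr an `attribution` with fold provenance ([explain_run()]), or
#'   a list of per-fold `attribution` objects.
#' @return scalar stability score in `[-1, 1]`.
#' @export
fold_stability <- function(attr) {
  if (inherits(attr, "attribution")) {
    if (is.null(attr$meta)) stop("attribution has no fold provenance",
                                 call. = FALSE)
    key <- paste(attr$meta$repeat_, attr$meta$fold)
    profiles <- lapply(unique(key), function(k) {
      colMeans(abs(attr$values[key == k, , drop = FALSE]))
    })
  } else {
    profiles <- lapply(attr, function(a) colMeans(abs(a$values)))
  }
  if (length(profiles) < 2) stop("need at least 2 folds", call. = FALSE)
  pairs <- combn(length(profiles), 2)
  mean(apply(pairs, 2, function(ij) {
    cor(profiles[[ij[1]]], profiles[[ij[2]]], method = "spearman")
  }))
}

#' Univariate confound-adjusted associations with BAG
#'
#' The traditional per-variable contrast: for each variable, the
#' standardized beta from an OLS of (standardized) BAG on the standardized
#' variable plus the confounds, together with the marginal Pearson
#' correlation and the regression p-value. Complete cases per variable.
#'
#' @param X exposome matrix.
#' @param bag BAG vector.
#' @param confounds optional confound matrix.
#' @return data frame with `variable`, `beta_std`, `r_marginal`, `p_value`,
#'   `n`.
#' @export
univariate_association <- function(X, bag, confounds = NULL) {
  X <- .assert_numeric_matrix(X)
  stopifnot(nrow(X) == length(bag))
  if (!is.null(confounds)) {
    confounds <- .assert_numeric_matrix(confounds, "confounds")
  }
  rows <- lapply(seq_len(ncol(X)), function(j) {
    ok <- !is.na(X[, j]) & !is.na(bag)
    x <- X[ok, j]; yb <- bag[ok]
    if (sd(x) == 0 || sd(yb) == 0) {
      return(data.frame(variable = colnames(X)[j], beta_std = NA_real_,
                        r_marginal = NA_real_, p_value = NA_real_,
                        n = sum(ok)))
    }
    zx <- (x - mean(x)) / sd(x)
    zy <- (yb - mean(yb)) / sd(yb)
    D <- if (is.null(confounds)) cbind(1, zx) else
      cbind(1, zx, confounds[ok, , drop = FALSE])
    fit <- lm.fit(D, zy)
    dfree <- sum(ok) - fit$rank
    sigma2 <- sum(fit$residuals^2) / dfree
    XtXinv <- chol2inv(chol(crossprod(D)))
    se <- sqrt(sigma2 * XtXinv[2, 2])
    tval <- fit$coefficients[2] / se
    data.frame(variable = colnames(X)[j],
               beta_std = unname(fit$coefficients[2]),
               r_marginal = cor(x, yb),
               p_value = 2 * stats::pt(-abs(tval), dfree),
               n = sum(ok))
  })
  do.call(rbind, rows)
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d samples x %d variables",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$meta)) {
    cat(sprintf(" (%d folds)", length(unique(paste(x$meta$repeat_,
                                                   x$meta$fold)))))
  }
  cat("\n")
  print(head(rank_contributions(x), 5))
  invisible(x)
}
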