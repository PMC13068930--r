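# End-to-end orchestration: simulate -> select healthy -> brain age ->
# bias-correct/BAG -> curate -> predict -> explain -> report, with strict
# separation of the model-building pool and the population set, and a
# machine-readable run manifest.

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a cohort, trains the brain-age model on the healthy members of
#' the model-building pool, computes bias-corrected BAG for the disjoint
#' population set, curates the exposome table, predicts BAG from it under
#' nested CV with permutation significance, explains the prediction, and
#' assembles a report with a ground-truth recovery scorecard.
#'
#' @param config a [cohort_config()] (its own seed drives generation).
#' @param effects named list of [effect_spec()]s.
#' @param seed integer seed for all analysis-stage randomness (folds,
#'   stochastic fits, permutations).
#' @param algorithm exposome-stage learner (`"random_forest"`, `"ridge"`,
#'   `"svr"`).
#' @param brainage_algorithms candidate learners for the brain-age stage.
#' @param brainage_cv a [cv_spec()]; default is a desk-scale
#'   5-fold x 1-repeat nested CV with a 20% age-stratified holdout.
#' @param prediction_spec a [prediction_cv_spec()]; default desk-scale
#'   5 outer folds x 1 repeat, 3 inner folds.
#' @param B permutations for the significance test.
#' @param retune re-tune hyperparameters inside permutations.
#' @param sex_as_predictor move sex from the confound set into the
#'   predictors.
#' @param n_min availability threshold; `NULL` scales the reference
#'   threshold of 2000 (defined against a 34k population) to the synthetic
#'   population size.
#' @param top_k rows of the contribution ranking reported.
#' @param explain compute Shapley attributions (first outer repeat).
#' @param outdir optional output directory; when given, all tables, the
#'   summary JSON and the run manifest are written there.
#' @return an object of class `expobag_run`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         effects = planted_effects(),
                         seed = 1,
                         algorithm = "random_forest",
                         brainage_algorithms = "ridge",
                         brainage_cv = NULL,
                         prediction_spec = NULL,
                         B = 99, retune = FALSE,
                         sex_as_predictor = FALSE,
                         n_min = NULL, top_k = 15, explain = TRUE,
                         outdir = NULL) {
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[3]
    timings[stage] <<- round(t1 - t0, 2)
    t0 <<- t1
  }

  ## simulate -----------------------------------------------------------------
  bundle <- generate_cohort(config, effects)
  parts <- bundle$participants
  gt <- bundle$ground_truth
  tick("simulate")

  ## participant sets ---------------------------------------------------------
  pool_ids <- parts$id[!parts$population]
  pop_ids <- parts$id[parts$population]
  healthy_ids <- intersect(select_healthy(parts), pool_ids)
  if (length(intersect(healthy_ids, pop_ids)) > 0) {
    stop("pipeline-integrity error: healthy training set overlaps the ",
         "population set", call. = FALSE)
  }
  tick("select_healthy")

  ## brain age ----------------------------------------------------------------
  finest <- max(config$granularity_levels)
  ba_cv <- brainage_cv %||% cv_spec(outer_folds = 5, outer_repeats = 1,
                                    inner_folds = 3, holdout_fraction = 0.2,
                                    seed = substream_seed(seed, 21))
  gm_fine <- bundle$gm[[as.character(finest)]]
  ages_h <- parts$age[match(healthy_ids, parts$id)]
  fits <- lapply(brainage_algorithms, function(alg) {
    train_candidate(gm_fine[healthy_ids, , drop = FALSE], ages_h,
                    model_candidate(alg, finest), ba_cv)
  })
  best <- select_best_model(fits)
  tick("brain_age")

  ## bias correction + BAG ----------------------------------------------------
  bias <- fit_bias_correction(best$oof$predicted, best$oof$age,
                              source = "healthy-train-out-of-fold")
  train_adj <- apply_correction(best$oof$predicted, bias)
  train_bag <- compute_bag(train_adj, best$oof$age,
                           id = healthy_ids[best$oof$row],
                           raw = best$oof$predicted)
  pred_pop <- predict_age(best, gm_fine[pop_ids, , drop = FALSE])
  adj_pop <- apply_correction(pred_pop, bias)
  ages_pop <- parts$age[match(pop_ids, parts$id)]
  bag_pop <- compute_bag(adj_pop, ages_pop, id = pop_ids, raw = pred_pop)
  tick("bag")

  ## exposome curation --------------------------------------------------------
  expo_pop <- bundle$exposome[match(pop_ids, bundle$exposome$id), ,
                              drop = FALSE]
  if (is.null(n_min)) {
    n_min <- max(20, round(2000 / 34365 * length(pop_ids)))
  }
  cur <- curate_exposome(expo_pop, bundle$specs, parts, n_min = n_min)
  retained <- setdiff(names(cur$table), "id")
  subsets <- build_subsets(cur$table, list(main = retained))
  main_ids <- subsets$main
  tick("curate")

  ## prediction ---------------------------------------------------------------
  X <- as.matrix(cur$table[match(main_ids, cur$table$id), retained,
                           drop = FALSE])
  y <- bag_pop$bag[match(main_ids, bag_pop$id)]
  conf <- confound_matrix(parts[match(main_ids, parts$id), , drop = FALSE])
  if (sex_as_predictor) {
    X <- cbind(X, sex = conf[, "sex"])
    conf <- conf[, setdiff(colnames(conf), "sex"), drop = FALSE]
  }
  spec <- prediction_spec %||% prediction_cv_spec(
    outer_folds = 5, outer_repeats = 1, inner_folds = 3,
    algorithm = algorithm, seed = substream_seed(seed, 31))
  run <- run_prediction(X, y, conf, spec, row_ids = main_ids)
  perm <- permutation_test(run, B = B, seed = substream_seed(seed, 32),
                           retune = retune)
  tick("predict")

  ## attribution --------------------------------------------------------------
  attrib <- ranks <- stability <- uni <- NULL
  if (explain) {
    attrib <- explain_run(run, repeats = 1)
    ranks <- rank_contributions(attrib)
    stability <- fold_stability(attrib)
    uni <- univariate_association(X, y, conf)
    tick("explain")
  }

  out <- structure(list(
    bundle = bundle, healthy_ids = healthy_ids, pop_ids = pop_ids,
    main_ids = main_ids, brainage_fits = fits, best = best, bias = bias,
    train_bag = train_bag, bag = bag_pop, curation = cur,
    subsets = subsets, X = X, y = y, confounds = conf, run = run,
    perm = perm, attributions = attrib, ranks = ranks,
    stability = stability, univariate = uni,
    seed = seed, timings = timings), class = "expobag_run")
  out$report <- report(out)

  if (!is.null(outdir)) .write_run(out, outdir)
  out
}

#' Summarize a pipeline run
#'
#' Assembles the machine-readable summary: model-selection table, BAG
#' distribution statistics, prediction metrics with permutation p and FDR
#' q, top contributing variables, attribution stability, and (for
#' synthetic cohorts) a ground-truth recovery scorecard. Missing stages
#' are noted, not fatal.
#'
#' @param run an `expobag_run`.
#' @return a named list (serializable to JSON).
#' @export
report <- function(run) {
  stopifnot(inherits(run, "expobag_run"))
  gt <- run$bundle$ground_truth
  gaps <- character(0)

  model_selection <- if (!is.null(run$brainage_fits)) {
    do.call(rbind, lapply(run$brainage_fits, function(f) {
      data.frame(candidate = f$candidate$name,
                 holdout_mae = f$evaluation$holdout_mae,
                 holdout_r = f$evaluation$holdout_r,
                 cv_mae = f$evaluation$cv_mae, cv_r = f$evaluation$cv_r)
    }))
  } else {
    gaps <- c(gaps, "brain-age stage missing"); NULL
  }

  bag_summary <- if (!is.null(run$bag)) {
    as.list(attr(run$bag, "summary"))
  } else {
    gaps <- c(gaps, "BAG stage missing"); NULL
  }

  prediction <- if (!is.null(run$run)) {
    list(algorithm = run$run$spec$algorithm, n = run$run$n,
         metrics = as.list(run$run$summary), pooled_r = run$run$pooled_r,
         p = as.list(run$perm$p), q = as.list(run$perm$q),
         B = run$perm$B, p_floor = permutation_p_floor(run$perm$B))
  } else {
    gaps <- c(gaps, "prediction stage missing"); NULL
  }

  top <- if (!is.null(run$ranks)) utils::head(run$ranks, 15) else {
    gaps <- c(gaps, "attribution stage missing"); NULL
  }

  scorecard <- NULL
  if (!is.null(run$ranks) && length(gt$truth_variables)) {
    tv <- intersect(gt$truth_variables, run$ranks$variable)
    er <- run$ranks$rank[match(tv, run$ranks$variable)]
    null_vars <- setdiff(run$ranks$variable, gt$truth_variables)
    nr <- run$ranks$rank[match(null_vars, run$ranks$variable)]
    mod <- names(Filter(function(e) e$kind == "moderator", gt$effects))
    mod_stats <- if (length(mod)) {
      m <- mod[1]
      list(variable = m,
           rank = run$ranks$rank[match(m, run$ranks$variable)],
           r_marginal = if (!is.null(run$univariate))
             run$univariate$r_marginal[match(m, run$univariate$variable)]
           else NA)
    }
    scorecard <- list(
      effect_variables = tv, effect_ranks = as.list(setNames(er, tv)),
      median_effect_rank = median(er), median_null_rank = median(nr),
      significant_pearson = !is.null(run$perm) &&
        run$perm$q[["pearson_r"]] < 0.05,
      moderator = mod_stats)
  }

  list(
    n_participants = nrow(run$bundle$participants),
    n_healthy_training = length(run$healthy_ids),
    n_population = length(run$pop_ids),
    n_main_subset = length(run$main_ids),
    model_selection = model_selection,
    best_candidate = if (!is.null(run$best)) run$best$candidate$name,
    bias_correction = if (!is.null(run$bias))
      list(slope = run$bias$slope, intercept = run$bias$intercept),
    train_bag_mean = if (!is.null(run$train_bag))
      unname(attr(run$train_bag, "summary")["mean"]),
    bag_summary = bag_summary,
    n_variables = if (!is.null(run$X)) ncol(run$X),
    prediction = prediction,
    top_contributions = top,
    fold_stability = run$stability,
    scorecard = scorecard,
    gaps = if (length(gaps)) gaps else NULL)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

.write_run <- function(run, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_cohort(run$bundle, file.path(outdir, "cohort"))
  .write_tsv(run$bag, file.path(outdir, "bag.tsv"))
  .write_tsv(run$curation$report, file.path(outdir, "curation_report.tsv"))
  .write_tsv(run$run$metrics, file.path(outdir, "prediction_metrics.tsv"))
  if (!is.null(run$ranks)) {
    .write_tsv(run$ranks, file.path(outdir, "contributions.tsv"))
  }
  if (!is.null(run$univariate)) {
    .write_tsv(run$univariate, file.path(outdir, "univariate.tsv"))
  }
  jsonlite::write_json(run$report, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", null = "null")
  files <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("expobag")),
    r_version = R.version.string,
    seed = run$seed,
    cohort_seed = run$bundle$ground_truth$config$seed,
    config = unclass(run$bundle$ground_truth$config),
    timings_sec = as.list(run$timings),
    file_md5 = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(outdir)
}

#' @export
print.expobag_run <- function(x, ...) {
  r <- x$report
  cat("expobag pipeline run\n")
  cat(sprintf("  cohort: %d participants (%d healthy training, %d population, %d main subset)\n",
              r$n_participants, r$n_healthy_training, r$n_population,
              r$n_main_subset))
  cat(sprintf("  brain age: %s, held-out MAE %.2f y, r %.3f\n",
              r$best_candidate,
              x$best$evaluation$holdout_mae, x$best$evaluation$holdout_r))
  cat(sprintf("  training BAG mean %.2e y; population BAG sd %.2f y\n",
              r$train_bag_mean, r$bag_summary$sd))
  if (!is.null(r$prediction)) {
    cat(sprintf("  exposome prediction (%s): r %.3f (p %.4g, q %.4g), R2 %.3f\n",
                r$prediction$algorithm, r$prediction$metrics$pearson_r,
                r$prediction$p$pearson_r, r$prediction$q$pearson_r,
                r$prediction$metrics$r_squared))
  }
  if (!is.null(r$scorecard)) {
    cat(sprintf("  recovery: median effect rank %.1f, median null rank %.1f, stability %.2f\n",
                r$scorecard$median_effect_rank, r$scorecard$median_null_rank,
                x$stability %||% NA))
  }
  invisible(x)
}
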