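# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes -- demographics, regional grey-matter volumes
# declining with an individual "effective brain age", and an exposome table
# with planted linear / nonlinear / duration / moderator / null effects on
# the aging deviation -- and exports the full ground truth so every stage of
# the pipeline can be tested against known answers.

#' Cohort generator configuration
#'
#' @param n_participants cohort size (`>= 2`).
#' @param age_range numeric length-2, chronological age bounds in years.
#' @param n_regions number of fine-granularity grey-matter regions.
#' @param granularity_levels region counts per granularity level; each must
#'   divide `n_regions` (coarser levels are grouped means of fine regions).
#' @param noise_sd_gm per-region Gaussian noise SD, volume units.
#' @param aging_slope_mean,aging_slope_sd mean and SD of the per-region
#'   volume loss per year of effective brain age.
#' @param deviation_sd SD of the residual (unexplained) aging deviation, in
#'   years, added on top of the planted exposure contributions.
#' @param nonhealthy_fraction fraction of participants flagged as failing at
#'   least one health-eligibility criterion; the flagged set is the top
#'   quantile of the absolute aging deviation.
#' @param population_fraction fraction of the cohort assigned to the
#'   population (exposome analysis) set; the remainder forms the
#'   model-building pool from which the healthy reference sample is drawn.
#'   The two sets are disjoint by construction.
#' @param missingness_blocks list of blocks, each a list with elements
#'   `name`, `variables` (character) and `fraction` (participant fraction
#'   whose cells in those variables are set missing).
#' @param seed integer seed; together with the configuration it fully
#'   determines the generated cohort (per-component substreams are derived
#'   with [substream_seed()]).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 3000,
                          age_range = c(44, 82),
                          n_regions = 100,
                          granularity_levels = c(100, 50, 25),
                          noise_sd_gm = 20,
                          aging_slope_mean = 1,
                          aging_slope_sd = 0.2,
                          deviation_sd = 2,
                          nonhealthy_fraction = 0.2,
                          population_fraction = 0.5,
                          missingness_blocks = list(),
                          seed = 1) {
  stopifnot(n_participants >= 2,
            length(age_range) == 2, age_range[1] < age_range[2],
            n_regions >= 1, length(granularity_levels) >= 1,
            noise_sd_gm >= 0, aging_slope_sd >= 0, deviation_sd >= 0,
            nonhealthy_fraction >= 0, nonhealthy_fraction < 1,
            population_fraction > 0, population_fraction < 1)
  if (any(n_regions %% granularity_levels != 0)) {
    stop("every granularity level must divide `n_regions`", call. = FALSE)
  }
  for (b in missingness_blocks) {
    stopifnot(is.character(b$variables), length(b$variables) >= 1,
              b$fraction >= 0, b$fraction <= 1)
  }
  structure(list(n_participants = as.integer(n_participants),
                 age_range = as.numeric(age_range),
                 n_regions = as.integer(n_regions),
                 granularity_levels = as.integer(granularity_levels),
                 noise_sd_gm = noise_sd_gm,
                 aging_slope_mean = aging_slope_mean,
                 aging_slope_sd = aging_slope_sd,
                 deviation_sd = deviation_sd,
                 nonhealthy_fraction = nonhealthy_fraction,
                 population_fraction = population_fraction,
                 missingness_blocks = missingness_blocks,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Planted exposure effect specification
#'
#' Describes one exposome variable: its sampling distribution and its
#' contribution, in years of aging deviation per SD of exposure, to the
#' individual aging deviation.
#'
#' Effect kinds: `linear` contributes `strength * z(x)`; `nonlinear`
#' contributes a standardized quadratic `strength * (z(x)^2 - 1)/sqrt(2)`;
#' `duration` emits an onset-age column (the analysis must derive the
#' duration itself) whose derived duration drives `strength * z(duration)`;
#' `moderator` and `interaction` contribute `strength * z(x) * z(partner)`,
#' a product that has zero marginal correlation with the variable itself;
#' `null` contributes nothing.
#'
#' @param name variable identifier (duration variables are emitted as
#'   `<name>_onset_age`).
#' @param kind effect kind, see Details.
#' @param strength contribution in years per SD; must be 0 for `null`.
#' @param partner partner variable name, required for moderator/interaction.
#' @param distribution list with `family` (`"normal"`, `"lognormal"`,
#'   `"ordinal"`, `"binary"`) and its parameters (`mean`/`sd`,
#'   `meanlog`/`sdlog`, `n_levels`, `prob`).
#' @param domain exposome domain label; defaults are assigned round-robin.
#' @param uninformative_codes numeric codes emitted as "do not know"-style
#'   responses for this variable (recorded in the variable dictionary).
#' @param uninformative_rate fraction of cells replaced by such codes.
#' @param aberrant_rate fraction of cells replaced by out-of-range values.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(name,
                        kind = c("null", "linear", "nonlinear", "duration",
                                 "moderator", "interaction"),
                        strength = 0, partner = NULL,
                        distribution = list(family = "normal", mean = 0, sd = 1),
                        domain = NULL,
                        uninformative_codes = NULL,
                        uninformative_rate = 0,
                        aberrant_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (kind == "null" && strength != 0) {
    stop("null effects must have strength 0", call. = FALSE)
  }
  if (kind %in% c("moderator", "interaction") && is.null(partner)) {
    stop(kind, " effects require a `partner` variable", call. = FALSE)
  }
  fam <- distribution$family %||% "normal"
  if (!fam %in% c("normal", "lognormal", "ordinal", "binary")) {
    stop("invalid distribution family: ", fam, call. = FALSE)
  }
  if (fam == "ordinal" && (distribution$n_levels %||% 4) < 2) {
    stop("ordinal distributions need `n_levels >= 2`", call. = FALSE)
  }
  if (fam == "binary" && !is.null(distribution$prob) &&
      (distribution$prob <= 0 || distribution$prob >= 1)) {
    stop("binary `prob` must be in (0, 1)", call. = FALSE)
  }
  structure(list(name = name, kind = kind, strength = strength,
                 partner = partner, distribution = distribution,
                 domain = domain, uninformative_codes = uninformative_codes,
                 uninformative_rate = uninformative_rate,
                 aberrant_rate = aberrant_rate),
            class = "effect_spec")
}

#' Default planted-effect set
#'
#' The study-condition effect list used throughout the package's synthetic
#' experiments: 10 effect variables (6 linear, 2 nonlinear, 1 duration-type,
#' 1 moderator whose partner is the strongest linear exposure) plus
#' `n_null` null variables spanning continuous, lognormal, ordinal and
#' binary distributions. Two ordinal null variables emit uninformative
#' codes (-1/-3) and one continuous null variable emits occasional
#' out-of-range values so the curation rules are exercised end to end.
#'
#' @param n_null number of null variables (default 50, for 60 in total).
#' @return named list of [effect_spec()] objects.
#' @export
planted_effects <- function(n_null = 50) {
  eff <- list(
    effect_spec("exp_linear_1", "linear", 2.5),
    effect_spec("exp_linear_2", "linear", 2.0),
    effect_spec("exp_linear_3", "linear", 1.75),
    effect_spec("exp_linear_4", "linear", 1.5,
                distribution = list(family = "lognormal", meanlog = 0, sdlog = 0.5)),
    effect_spec("exp_linear_5", "linear", 1.25),
    effect_spec("exp_linear_6", "linear", 1.25,
                distribution = list(family = "ordinal", n_levels = 5)),
    effect_spec("exp_nonlin_1", "nonlinear", 1.75),
    effect_spec("exp_nonlin_2", "nonlinear", 1.5),
    effect_spec("exp_condition", "duration", 1.75),
    effect_spec("exp_moderator_1", "moderator", 2.5, partner = "exp_linear_1")
  )
  fams <- rep(c("normal", "normal", "lognormal", "ordinal", "binary"),
              length.out = n_null)
  nulls <- lapply(seq_len(n_null), function(i) {
    dist <- switch(fams[i],
      normal = list(family = "normal", mean = 0, sd = 1),
      lognormal = list(family = "lognormal", meanlog = 0, sdlog = 0.5),
      ordinal = list(family = "ordinal", n_levels = 4),
      binary = list(family = "binary", prob = 0.3))
    effect_spec(sprintf("exp_null_%02d", i), "null", 0, distribution = dist,
                uninformative_codes = if (fams[i] == "ordinal" && i <= 10) c(-1, -3),
                uninformative_rate = if (fams[i] == "ordinal" && i <= 10) 0.02 else 0,
                aberrant_rate = if (i == 7) 0.01 else 0)
  })
  out <- c(eff, nulls)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

.draw_variable <- function(spec, n) {
  d <- spec$distribution
  switch(d$family %||% "normal",
    normal = rnorm(n, d$mean %||% 0, d$sd %||% 1),
    lognormal = stats::rlnorm(n, d$meanlog %||% 0, d$sdlog %||% 0.5),
    ordinal = sample.int(d$n_levels %||% 4, n, replace = TRUE),
    binary = rbinom(n, 1, d$prob %||% 0.5))
}

.zscore <- function(x) {
  s <- sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Generate a synthetic cohort
#'
#' Draws demographics, exposome variables, the individual aging deviation
#' `d` (sum of planted contributions plus Gaussian noise), regional
#' grey-matter volumes declining with the effective brain age
#' (`age + d`), health-eligibility flags, the model-pool/population split,
#' and block-structured missingness. Everything is a pure function of the
#' configuration and its seed.
#'
#' @param config a [cohort_config()].
#' @param effects named list of [effect_spec()] objects (unique names);
#'   default [planted_effects()].
#' @return an object of class `cohort_bundle`: a list with elements
#'   `participants` (demographics, confounds, eligibility flags, subset
#'   membership), `gm` (named list of participants x regions matrices, one
#'   per granularity level), `exposome` (id + variable columns, with
#'   missingness and special codes applied), `specs` (variable dictionary
#'   for the curation stage) and `ground_truth` (per-participant deviation
#'   and contributions, per-region aging parameters, effect specs, seeds).
#' @export
generate_cohort <- function(config = cohort_config(), effects = planted_effects()) {
  stopifnot(inherits(config, "cohort_config"))
  nm <- vapply(effects, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate variable names in `effects`", call. = FALSE)
  names(effects) <- nm
  for (e in effects) {
    if (e$kind %in% c("moderator", "interaction") && !e$partner %in% nm) {
      stop("partner '", e$partner, "' of '", e$name,
           "' is not in the variable set", call. = FALSE)
    }
  }
  n <- config$n_participants
  seeds <- vapply(0:7, function(k) substream_seed(config$seed, k), integer(1))
  names(seeds) <- c("demographics", "exposome", "deviation", "gm_params",
                    "gm_noise", "flags", "missingness", "split")

  ## demographics ------------------------------------------------------------
  set.seed(seeds["demographics"])
  age <- runif(n, config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, 0.5)                       # 1 = male, 0 = female
  height <- ifelse(sex == 1, rnorm(n, 176, 7), rnorm(n, 163, 6))
  vol_scaling <- rnorm(n, 1, 0.05)
  id <- sprintf("P%05d", seq_len(n))

  ## exposome draws + contributions ------------------------------------------
  set.seed(seeds["exposome"])
  raw <- list()          # columns as emitted (onset ages for duration kind)
  zvals <- list()        # standardized working values per effect variable
  truth_names <- character(0)
  col_of <- character(0) # exposome column name per effect name
  for (e in effects) {
    if (e$kind == "duration") {
      dur <- runif(n, 0, pmin(40, age - 20))
      onset <- age - dur
      cn <- paste0(e$name, "_onset_age")
      raw[[cn]] <- onset
      zvals[[e$name]] <- .zscore(dur)
      col_of[e$name] <- cn
    } else {
      x <- .draw_variable(e, n)
      raw[[e$name]] <- x
      zvals[[e$name]] <- .zscore(x)
      col_of[e$name] <- e$name
    }
  }
  contrib_cols <- list()
  for (e in effects) {
    if (e$kind == "null" || e$strength == 0) next
    ctb <- switch(e$kind,
      linear = e$strength * zvals[[e$name]],
      duration = e$strength * zvals[[e$name]],
      nonlinear = e$strength * (zvals[[e$name]]^2 - 1) / sqrt(2),
      moderator = e$strength * zvals[[e$name]] * zvals[[e$partner]],
      interaction = e$strength * zvals[[e$name]] * zvals[[e$partner]])
    tn <- if (e$kind == "duration") paste0(e$name, "_duration") else e$name
    contrib_cols[[tn]] <- ctb
    truth_names <- c(truth_names, tn)
  }
  contrib <- if (length(contrib_cols)) {
    do.call(cbind, contrib_cols)
  } else {
    matrix(0, n, 0)
  }

  set.seed(seeds["deviation"])
  d <- rowSums(contrib) + rnorm(n, 0, config$deviation_sd)
  effective_age <- age + d

  ## grey-matter features -----------------------------------------------------
  m <- config$n_regions
  set.seed(seeds["gm_params"])
  region_params <- data.frame(
    region = sprintf("r%03d", seq_len(m)),
    intercept = rnorm(m, 500, 50),
    slope = pmax(rnorm(m, config$aging_slope_mean, config$aging_slope_sd), 0.05),
    sex_offset = rnorm(m, 0, 5),
    height_coef = rnorm(m, 0.5, 0.2),
    scaling_coef = rnorm(m, 50, 10))
  set.seed(seeds["gm_noise"])
  base <- outer(rep(1, n), region_params$intercept) -
    outer(effective_age, region_params$slope) +
    outer(sex, region_params$sex_offset) +
    outer(height - 170, region_params$height_coef) +
    outer(vol_scaling - 1, region_params$scaling_coef)
  gm_fine <- base + matrix(rnorm(n * m, 0, config$noise_sd_gm), n, m)
  rownames(gm_fine) <- id
  colnames(gm_fine) <- region_params$region
  gm <- list()
  for (lev in config$granularity_levels) {
    grp <- rep(seq_len(lev), each = m / lev)
    gl <- t(apply(gm_fine, 1, function(r) tapply(r, grp, mean)))
    colnames(gl) <- sprintf("lvl%d_r%03d", lev, seq_len(lev))
    rownames(gl) <- id
    gm[[as.character(lev)]] <- gl
  }

  ## health-eligibility flags -------------------------------------------------
  set.seed(seeds["flags"])
  k <- round(config$nonhealthy_fraction * n)
  flagged <- rep(FALSE, n)
  if (k > 0) flagged[order(-abs(d))[seq_len(k)]] <- TRUE
  long_standing_illness <- diabetes <- stroke <- icd10_diagnosis <- rep(FALSE, n)
  self_rated_health <- sample(1:2, n, replace = TRUE)   # 1 excellent .. 4 poor
  crit <- c("long_standing_illness", "diabetes", "stroke", "icd10_diagnosis",
            "self_rated_health")
  for (i in which(flagged)) {
    fail <- sample(crit, sample(1:2, 1))
    if ("long_standing_illness" %in% fail) long_standing_illness[i] <- TRUE
    if ("diabetes" %in% fail) diabetes[i] <- TRUE
    if ("stroke" %in% fail) stroke[i] <- TRUE
    if ("icd10_diagnosis" %in% fail) icd10_diagnosis[i] <- TRUE
    if ("self_rated_health" %in% fail) self_rated_health[i] <- sample(3:4, 1)
  }

  ## population / model-pool split --------------------------------------------
  set.seed(seeds["split"])
  pop <- rep(FALSE, n)
  pop[sample.int(n, round(config$population_fraction * n))] <- TRUE

  participants <- data.frame(
    id = id, age = age, sex = sex, height = height, vol_scaling = vol_scaling,
    long_standing_illness = long_standing_illness, diabetes = diabetes,
    stroke = stroke, icd10_diagnosis = icd10_diagnosis,
    self_rated_health = self_rated_health,
    population = pop, stringsAsFactors = FALSE)

  ## exposome table: special codes, aberrant values, missingness --------------
  exposome <- data.frame(id = id, raw, check.names = FALSE,
                         stringsAsFactors = FALSE)
  specs <- .build_variable_specs(effects, col_of)
  set.seed(seeds["missingness"])
  injected <- list()
  for (e in effects) {
    cn <- col_of[e$name]
    if (e$uninformative_rate > 0 && length(e$uninformative_codes)) {
      hit <- which(runif(n) < e$uninformative_rate)
      exposome[hit, cn] <- sample(e$uninformative_codes, length(hit),
                                  replace = TRUE)
      injected$uninformative[[cn]] <- length(hit)
    }
    if (e$aberrant_rate > 0) {
      hit <- which(runif(n) < e$aberrant_rate)
      vmax <- specs$valid_max[specs$name == cn]
      exposome[hit, cn] <- vmax + 10 + abs(rnorm(length(hit), 0, 5))
      injected$aberrant[[cn]] <- length(hit)
    }
  }
  block_members <- list()
  for (b in config$missingness_blocks) {
    bad <- setdiff(b$variables, names(exposome))
    if (length(bad)) stop("missingness block names unknown variables: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    rows <- sample.int(n, round(b$fraction * n))
    for (v in b$variables) exposome[rows, v] <- NA
    block_members[[b$name %||% paste(b$variables, collapse = "+")]] <- id[rows]
  }

  ground_truth <- list(
    d = setNames(d, id), effective_age = setNames(effective_age, id),
    contributions = `rownames<-`(contrib, id),
    effects = effects, effect_columns = col_of,
    truth_variables = truth_names,
    region_params = region_params, seeds = seeds, config = config,
    injected = injected, missing_blocks = block_members)

  structure(list(participants = participants, gm = gm, exposome = exposome,
                 specs = specs, ground_truth = ground_truth),
            class = "cohort_bundle")
}

.build_variable_specs <- function(effects, col_of) {
  domains <- c("biomedical", "lifestyle", "socio-affective/mental",
               "early-life", "environmental", "socio-economic")
  rows <- lapply(seq_along(effects), function(i) {
    e <- effects[[i]]
    cn <- col_of[e$name]
    fam <- e$distribution$family %||% "normal"
    if (e$kind == "duration") {
      data.frame(name = cn, domain = e$domain %||% "biomedical",
                 dtype = "continuous", valid_min = 0, valid_max = 100,
                 valid_categories = "", uninformative_codes = "",
                 is_onset_age = TRUE, stringsAsFactors = FALSE)
    } else {
      dtype <- switch(fam, normal = "continuous", lognormal = "continuous",
                      ordinal = "ordinal", binary = "binary")
      rng <- switch(fam,
        normal = (e$distribution$mean %||% 0) +
          c(-8, 8) * (e$distribution$sd %||% 1),
        lognormal = c(0, exp((e$distribution$meanlog %||% 0) +
                             8 * (e$distribution$sdlog %||% 0.5))),
        ordinal = c(1, e$distribution$n_levels %||% 4),
        binary = c(0, 1))
      cats <- switch(fam,
        ordinal = paste(seq_len(e$distribution$n_levels %||% 4), collapse = ","),
        binary = "0,1", "")
      data.frame(name = cn, domain = e$domain %||% domains[(i - 1) %% 6 + 1],
                 dtype = dtype, valid_min = rng[1], valid_max = rng[2],
                 valid_categories = cats,
                 uninformative_codes = paste(e$uninformative_codes, collapse = ","),
                 is_onset_age = FALSE, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cfg <- x$ground_truth$config
  cat("Synthetic cohort:", cfg$n_participants, "participants,",
      length(x$exposome) - 1, "exposome variables,",
      cfg$n_regions, "fine grey-matter regions\n")
  cat("  granularity levels:", paste(cfg$granularity_levels, collapse = ", "), "\n")
  cat("  population set:", sum(x$participants$population), "| model pool:",
      sum(!x$participants$population), "\n")
  cat("  aging deviation d: mean", round(mean(x$ground_truth$d), 3), "sd",
      round(sd(x$ground_truth$d), 3), "\n")
  invisible(x)
}

.format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

#' Write a cohort bundle to disk
#'
#' Emits deterministic CSV files (participants, exposome, one grey-matter
#' file per granularity level, variable dictionary, per-participant ground
#' truth) plus a JSON file echoing the configuration, the effect
#' specifications and the substream seeds. Numeric values are written with
#' round-trip precision so [read_cohort()] reproduces the bundle exactly.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", dir, call. = FALSE)
  }
  wr <- function(df, f) {
    write.csv(.format_num_df(df), file.path(dir, f), row.names = FALSE,
              quote = TRUE, na = "")
  }
  wr(bundle$participants, "participants.csv")
  wr(bundle$exposome, "exposome.csv")
  wr(bundle$specs, "variable_specs.csv")
  for (lev in names(bundle$gm)) {
    wr(data.frame(id = rownames(bundle$gm[[lev]]), bundle$gm[[lev]],
                  check.names = FALSE), sprintf("gm_%s.csv", lev))
  }
  gt <- bundle$ground_truth
  gtdf <- data.frame(id = names(gt$d), d = unname(gt$d),
                     effective_age = unname(gt$effective_age))
  if (ncol(gt$contributions) > 0) {
    gtdf <- cbind(gtdf, as.data.frame(gt$contributions)[,
      colnames(gt$contributions), drop = FALSE])
  }
  wr(gtdf, "ground_truth.csv")
  wr(gt$region_params, "region_params.csv")
  meta <- list(
    config = unclass(gt$config),
    effects = lapply(gt$effects, unclass),
    seeds = as.list(gt$seeds),
    truth_variables = gt$truth_variables,
    missing_blocks = gt$missing_blocks)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir directory containing the bundle files.
#' @return a `cohort_bundle` equal, field by field, to the one written.
#' @export
read_cohort <- function(dir) {
  rd <- function(f, ...) read.csv(file.path(dir, f), stringsAsFactors = FALSE, ...)
  participants <- rd("participants.csv")
  for (cl in c("long_standing_illness", "diabetes", "stroke",
               "icd10_diagnosis", "population")) {
    participants[[cl]] <- as.logical(participants[[cl]])
  }
  exposome <- rd("exposome.csv", check.names = FALSE)
  specs <- rd("variable_specs.csv")
  specs$valid_categories[is.na(specs$valid_categories)] <- ""
  specs$uninformative_codes[is.na(specs$uninformative_codes)] <- ""
  specs$is_onset_age <- as.logical(specs$is_onset_age)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  cfg <- meta$config
  config <- cohort_config(
    n_participants = cfg$n_participants,
    age_range = unlist(cfg$age_range),
    n_regions = cfg$n_regions,
    granularity_levels = unlist(cfg$granularity_levels),
    noise_sd_gm = cfg$noise_sd_gm, aging_slope_mean = cfg$aging_slope_mean,
    aging_slope_sd = cfg$aging_slope_sd, deviation_sd = cfg$deviation_sd,
    nonhealthy_fraction = cfg$nonhealthy_fraction,
    population_fraction = cfg$population_fraction,
    missingness_blocks = lapply(cfg$missingness_blocks, function(b) {
      list(name = b$name, variables = unlist(b$variables), fraction = b$fraction)
    }),
    seed = cfg$seed)
  effects <- lapply(meta$effects, function(e) {
    effect_spec(e$name, e$kind, e$strength, partner = e$partner,
                distribution = e$distribution, domain = e$domain,
                uninformative_codes = unlist(e$uninformative_codes),
                uninformative_rate = e$uninformative_rate,
                aberrant_rate = e$aberrant_rate)
  })
  names(effects) <- vapply(effects, `[[`, "", "name")
  gm <- list()
  for (lev in as.character(config$granularity_levels)) {
    df <- rd(sprintf("gm_%s.csv", lev), check.names = FALSE)
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$id
    gm[[lev]] <- mat
  }
  gtdf <- rd("ground_truth.csv", check.names = FALSE)
  region_params <- rd("region_params.csv")
  contrib <- as.matrix(gtdf[, setdiff(names(gtdf), c("id", "d", "effective_age")),
                            drop = FALSE])
  rownames(contrib) <- gtdf$id
  seeds <- vapply(0:7, function(k) substream_seed(config$seed, k), integer(1))
  names(seeds) <- c("demographics", "exposome", "deviation", "gm_params",
                    "gm_noise", "flags", "missingness", "split")
  col_of <- vapply(effects, function(e) {
    if (e$kind == "duration") paste0(e$name, "_onset_age") else e$name
  }, "")
  ground_truth <- list(
    d = setNames(gtdf$d, gtdf$id),
    effective_age = setNames(gtdf$effective_age, gtdf$id),
    contributions = contrib, effects = effects, effect_columns = col_of,
    truth_variables = unlist(meta$truth_variables),
    region_params = region_params, seeds = seeds, config = config,
    injected = list(),
    missing_blocks = lapply(meta$missing_blocks, unlist))
  structure(list(participants = participants, gm = gm, exposome = exposome,
                 specs = specs, ground_truth = ground_truth),
            class = "cohort_bundle")
}
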