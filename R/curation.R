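# Exposome curation: uniqueness of records, aberrant and uninformative
# value exclusion, duration derivation from onset ages, minimum-availability
# filtering, analysis-subset construction and the redundancy heatmap.
# No step ever imputes a value; each step appends to an audit log carried
# on the table (`curation_report()`), so counts reconcile exactly with
# cell-level changes.

.cur_log <- function(table) attr(table, "curation_log") %||% list()

.cur_append <- function(table, step, df) {
  log <- .cur_log(table)
  log[[length(log) + 1]] <- cbind(step = step, df, stringsAsFactors = FALSE)
  attr(table, "curation_log") <- log
  table
}

.var_cols <- function(table) setdiff(names(table), "id")

#' Curation audit report
#'
#' @param table an exposome table that has passed through curation steps, or
#'   the list returned by [filter_min_availability()].
#' @return a data frame with one row per (step, variable) count.
#' @export
curation_report <- function(table) {
  if (is.list(table) && !is.data.frame(table) && !is.null(table$report)) {
    return(table$report)
  }
  log <- .cur_log(table)
  if (!length(log)) {
    return(data.frame(step = character(0), variable = character(0),
                      count = integer(0), note = character(0)))
  }
  do.call(rbind, log)
}

#' Enforce uniqueness of participant records
#'
#' Removes duplicate rows per participant id, keeping the first occurrence.
#' Conflicting duplicates (two different non-missing values for the same
#' cell) are kept-first as well and logged.
#'
#' @param table exposome table with an `id` column.
#' @return the de-duplicated table, with the removal counts appended to its
#'   curation log.
#' @export
enforce_uniqueness <- function(table) {
  if (!"id" %in% names(table)) .stop_schema("exposome table has no `id` column")
  dup <- duplicated(table$id)
  n_conflict <- 0L
  if (any(dup)) {
    first <- table[!dup, , drop = FALSE]
    for (i in which(dup)) {
      j <- match(table$id[i], first$id)
      for (v in .var_cols(table)) {
        a <- first[[v]][j]; b <- table[[v]][i]
        if (!is.na(a) && !is.na(b) && a != b) n_conflict <- n_conflict + 1L
      }
    }
    out <- first
  } else {
    out <- table
  }
  rownames(out) <- NULL
  .cur_append(out, "uniqueness",
              data.frame(variable = "(rows)", count = sum(dup),
                         note = sprintf("%d conflicting cells kept-first",
                                        n_conflict)))
}

.spec_row <- function(specs, v) {
  i <- match(v, specs$name)
  if (is.na(i)) .stop_schema("no variable spec for column `", v, "`")
  specs[i, , drop = FALSE]
}

#' Null out-of-range and invalid-category values
#'
#' Continuous and ordinal variables are checked against
#' `[valid_min, valid_max]`; categorical/ordinal variables with a category
#' set against that set. Offending cells are set missing (never imputed)
#' and counted per variable.
#'
#' @param table exposome table.
#' @param specs variable dictionary (one row per variable column).
#' @return the validated table with counts appended to its curation log.
#' @export
validate_values <- function(table, specs) {
  counts <- integer(0)
  for (v in .var_cols(table)) {
    sp <- .spec_row(specs, v)
    x <- table[[v]]
    bad <- rep(FALSE, length(x))
    codes <- .parse_codes(sp$uninformative_codes)
    excuse <- if (length(codes)) x %in% codes else rep(FALSE, length(x))
    if (nzchar(sp$valid_categories %||% "")) {
      cats <- as.numeric(strsplit(sp$valid_categories, ",")[[1]])
      bad <- !is.na(x) & !(x %in% cats) & !excuse
    } else {
      bad <- !is.na(x) & (x < sp$valid_min | x > sp$valid_max) & !excuse
    }
    table[[v]][bad] <- NA
    counts[v] <- sum(bad)
  }
  .cur_append(table, "aberrant",
              data.frame(variable = names(counts), count = unname(counts),
                         note = ""))
}

.parse_codes <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(s)) return(numeric(0))
  as.numeric(strsplit(s, ",")[[1]])
}

#' Null uninformative response codes
#'
#' Cells equal to a variable's configured uninformative codes ("do not
#' know" / "prefer not to answer" analogues) are set missing and counted.
#' Variables without configured codes pass through unchanged.
#'
#' @inheritParams validate_values
#' @return the table with counts appended to its curation log.
#' @export
drop_uninformative <- function(table, specs) {
  counts <- integer(0)
  for (v in .var_cols(table)) {
    sp <- .spec_row(specs, v)
    codes <- .parse_codes(sp$uninformative_codes)
    if (length(codes)) {
      bad <- !is.na(table[[v]]) & table[[v]] %in% codes
      table[[v]][bad] <- NA
      counts[v] <- sum(bad)
    } else {
      counts[v] <- 0L
    }
  }
  .cur_append(table, "uninformative",
              data.frame(variable = names(counts), count = unname(counts),
                         note = ""))
}

#' Derive exposure durations from onset ages
#'
#' For every variable flagged `is_onset_age`, adds (or recomputes) a
#' `*_duration` column as assessment age minus onset age. Missing onsets
#' yield missing durations; onsets after the assessment age are
#' inconsistent, yield missing durations, and are logged.
#'
#' @param table exposome table.
#' @param participants participant table providing the assessment age
#'   (`age` column) per id.
#' @param specs variable dictionary; onset variables must be flagged.
#' @return the table with duration columns, counts appended to its log.
#' @export
derive_durations <- function(table, participants, specs) {
  if (!all(c("id", "age") %in% names(participants))) {
    .stop_schema("participant table must have `id` and `age` columns")
  }
  assess <- participants$age[match(table$id, participants$id)]
  if (anyNA(assess)) .stop_schema("assessment age missing for some participants")
  onset_vars <- intersect(specs$name[specs$is_onset_age], .var_cols(table))
  rows <- list()
  for (v in onset_vars) {
    dv <- if (grepl("_onset_age$", v)) sub("_onset_age$", "_duration", v) else
      paste0(v, "_duration")
    dur <- assess - table[[v]]
    inconsistent <- !is.na(dur) & dur < 0
    dur[inconsistent] <- NA
    table[[dv]] <- dur
    rows[[v]] <- data.frame(variable = dv, count = sum(inconsistent),
                            note = sprintf("from %s; %d onset > assessment",
                                           v, sum(inconsistent)))
  }
  if (!length(rows)) return(table)
  .cur_append(table, "duration", do.call(rbind, rows))
}

#' Extend a variable dictionary with derived duration variables
#'
#' @param specs variable dictionary.
#' @return `specs` with one continuous row per onset variable's duration
#'   (range 0-100 years), if not already present.
#' @export
duration_specs <- function(specs) {
  for (v in specs$name[specs$is_onset_age]) {
    dv <- if (grepl("_onset_age$", v)) sub("_onset_age$", "_duration", v) else
      paste0(v, "_duration")
    if (!dv %in% specs$name) {
      specs <- rbind(specs, data.frame(
        name = dv, domain = specs$domain[specs$name == v],
        dtype = "continuous", valid_min = 0, valid_max = 100,
        valid_categories = "", uninformative_codes = "",
        is_onset_age = FALSE, stringsAsFactors = FALSE))
    }
  }
  specs
}

#' Filter variables by minimum availability
#'
#' Drops variables observed in fewer than `n_min` participants, or (when
#' `require_both_sexes`) observed in only one sex. The boundary is
#' inclusive: a variable observed in exactly `n_min` participants of both
#' sexes is retained.
#'
#' @param table exposome table.
#' @param participants participant table with `id` and `sex`.
#' @param n_min minimum number of non-missing values (`>= 1`).
#' @param require_both_sexes require non-missing values in both sexes.
#' @return list with `table` (retained columns) and `report` (the full
#'   curation audit including the drop decisions).
#' @export
filter_min_availability <- function(table, participants, n_min = 2000,
                                    require_both_sexes = TRUE) {
  stopifnot(n_min >= 1)
  sex <- participants$sex[match(table$id, participants$id)]
  dropped <- character(0); reason <- character(0)
  for (v in .var_cols(table)) {
    obs <- !is.na(table[[v]])
    if (sum(obs) < n_min) {
      dropped <- c(dropped, v)
      reason <- c(reason, sprintf("available in %d < %d participants",
                                  sum(obs), n_min))
    } else if (require_both_sexes && length(unique(sex[obs])) < 2) {
      dropped <- c(dropped, v)
      reason <- c(reason, "observed in a single sex only")
    }
  }
  out <- table[, c("id", setdiff(.var_cols(table), dropped)), drop = FALSE]
  attr(out, "curation_log") <- .cur_log(table)
  out <- .cur_append(out, "availability",
                     if (length(dropped)) {
                       data.frame(variable = dropped, count = 1L, note = reason)
                     } else {
                       data.frame(variable = "(none)", count = 0L, note = "")
                     })
  list(table = out, report = curation_report(out))
}

#' Build complete-case analysis subsets
#'
#' For each named variable set, returns the participants with no missing
#' value on any listed variable. An empty variable list returns everyone;
#' nested variable sets yield reverse-nested participant sets.
#'
#' @param table exposome table.
#' @param variable_sets named list of character vectors (must be retained
#'   columns of `table`).
#' @return named list of participant-id character vectors.
#' @export
build_subsets <- function(table, variable_sets) {
  stopifnot(is.list(variable_sets), length(names(variable_sets)) ==
              length(variable_sets))
  out <- list()
  for (nm in names(variable_sets)) {
    vars <- variable_sets[[nm]]
    unknown <- setdiff(vars, .var_cols(table))
    if (length(unknown)) {
      stop("unknown variable(s) in set '", nm, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- if (length(vars) == 0) rep(TRUE, nrow(table)) else
      complete.cases(table[, vars, drop = FALSE])
    out[[nm]] <- table$id[keep]
  }
  out
}

#' Pairwise variable redundancy matrix
#'
#' Pearson correlations on pairwise-complete observations (block
#' missingness makes listwise deletion empty). Zero-variance variables
#' yield `NA` entries and are reported in the `zero_variance` attribute.
#'
#' @param table exposome table (`>= 2` variable columns).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
redundancy_heatmap <- function(table) {
  vars <- .var_cols(table)
  if (length(vars) < 2) stop("need at least 2 variables", call. = FALSE)
  X <- as.matrix(table[, vars, drop = FALSE])
  zv <- vars[apply(X, 2, function(x) sd(x, na.rm = TRUE) == 0 ||
                     all(is.na(x)))]
  suppressWarnings(cm <- cor(X, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  attr(cm, "zero_variance") <- zv
  cm
}

#' Run the full curation chain
#'
#' uniqueness -> aberrant-value exclusion -> uninformative-value exclusion
#' -> duration derivation -> minimum-availability filter. The chain is
#' idempotent and never imputes.
#'
#' @param table exposome table.
#' @param specs variable dictionary.
#' @param participants participant table (assessment age, sex).
#' @param n_min minimum availability (see [filter_min_availability()]).
#' @param require_both_sexes require both sexes per variable.
#' @return list with `table`, `specs` (extended with duration variables)
#'   and `report`.
#' @export
curate_exposome <- function(table, specs, participants, n_min = 2000,
                            require_both_sexes = TRUE) {
  table <- enforce_uniqueness(table)
  table <- validate_values(table, specs)
  table <- drop_uninformative(table, specs)
  table <- derive_durations(table, participants, specs)
  specs2 <- duration_specs(specs)
  table <- validate_values(table, specs2)   # range-check derived durations
  fl <- filter_min_availability(table, participants, n_min,
                                require_both_sexes)
  list(table = fl$table, specs = specs2, report = fl$report)
}
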