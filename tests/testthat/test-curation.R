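mk_specs <- function(names, dtype = "continuous", vmin = -10, vmax = 10,
                     cats = "", codes = "", onset = FALSE) {
  data.frame(name = names, domain = "biomedical", dtype = dtype,
             valid_min = vmin, valid_max = vmax, valid_categories = cats,
             uninformative_codes = codes, is_onset_age = onset,
             stringsAsFactors = FALSE)
}

test_that("uniqueness keeps the first record and logs conflicts", {
  tab <- data.frame(id = c("a", "b", "c"), v = c(1, 2, 3))
  out <- enforce_uniqueness(tab)
  expect_equal(out[, c("id", "v")], tab)
  rep0 <- curation_report(out)
  expect_identical(rep0$count[rep0$step == "uniqueness"], 0L)

  tab2 <- rbind(tab, data.frame(id = "b", v = 2))           # exact duplicate
  out2 <- enforce_uniqueness(tab2)
  expect_identical(nrow(out2), 3L)
  expect_identical(curation_report(out2)$count, 1L)

  tab3 <- rbind(tab, data.frame(id = "b", v = 99))          # conflicting cell
  out3 <- enforce_uniqueness(tab3)
  expect_identical(out3$v[out3$id == "b"], 2)               # first kept
  expect_match(curation_report(out3)$note, "1 conflicting")
  expect_error(enforce_uniqueness(data.frame(v = 1)), "id")
})

test_that("aberrant values are nulled against range or category set, with exact counts", {
  tab <- data.frame(id = paste0("p", 1:10),
                    cont = c(5, -50, 5, 5, 50, 5, 5, 5, 99, 5),
                    cat = c(1, 2, 3, 7, 1, 2, 9, 1, 2, 8))
  specs <- rbind(mk_specs("cont"),
                 mk_specs("cat", dtype = "categorical", cats = "1,2,3"))
  out <- validate_values(tab, specs)
  expect_identical(sum(is.na(out$cont)), 3L)   # -50, 50, 99 out of [-10, 10]
  expect_identical(sum(is.na(out$cat)), 3L)    # 7, 9, 8 not in {1,2,3}
  rep <- curation_report(out)
  expect_identical(sum(rep$count[rep$step == "aberrant"]), 6L)
  # in-range values untouched
  expect_identical(out$cont[1], 5)
  expect_error(validate_values(tab, mk_specs("cont")), "no variable spec")
})

test_that("uninformative codes are nulled only where configured", {
  tab <- data.frame(id = paste0("p", 1:6),
                    a = c(1, -1, 2, -3, 1, 2), b = c(1, -1, 2, 2, 1, 1))
  specs <- rbind(mk_specs("a", dtype = "ordinal", cats = "1,2", codes = "-1,-3"),
                 mk_specs("b", vmin = -5, vmax = 5))
  out <- drop_uninformative(tab, specs)
  expect_identical(sum(is.na(out$a)), 2L)
  expect_identical(out$b, tab$b)               # no codes configured: unchanged
  rep <- curation_report(out)
  expect_identical(rep$count[rep$variable == "a"], 2L)
  expect_identical(rep$count[rep$variable == "b"], 0L)
})

test_that("durations are derived from onset ages with inconsistencies logged", {
  parts <- data.frame(id = c("p1", "p2", "p3"), age = c(60, 60, 60))
  tab <- data.frame(id = c("p1", "p2", "p3"),
                    cond_onset_age = c(50, NA, 65))
  specs <- mk_specs("cond_onset_age", vmin = 0, vmax = 100, onset = TRUE)
  out <- derive_durations(tab, parts, specs)
  expect_equal(out$cond_duration, c(10, NA, NA))
  rep <- curation_report(out)
  expect_identical(rep$count[rep$variable == "cond_duration"], 1L)
  expect_error(derive_durations(tab, data.frame(id = "p1"), specs),
               "`id` and `age`")
})

test_that("availability filter uses an inclusive threshold and requires both sexes", {
  n <- 12
  parts <- data.frame(id = paste0("p", 1:n), age = 60,
                      sex = rep(c(0, 1), 6))
  tab <- data.frame(id = parts$id,
                    v1999 = c(rep(1, 4), rep(NA, 8)),     # below threshold
                    v2000 = c(rep(1, 5), rep(NA, 7)),     # exactly at threshold
                    v2001 = c(rep(1, 6), rep(NA, 6)),
                    vfem = ifelse(parts$sex == 0, 1, NA)) # single sex
  fl <- filter_min_availability(tab, parts, n_min = 5)
  expect_setequal(setdiff(names(fl$table), "id"), c("v2000", "v2001"))
  expect_setequal(fl$report$variable[fl$report$step == "availability"],
                  c("v1999", "vfem"))
})

test_that("complete-case subsets are monotone and match the planted block arithmetic", {
  blocks <- list(
    list(name = "A", variables = c("null_01", "null_02"), fraction = 0.3),
    list(name = "B", variables = "null_03", fraction = 0.15))
  cfg <- cohort_config(n_participants = 300, n_regions = 10,
                       granularity_levels = 10, seed = 13,
                       missingness_blocks = blocks)
  b <- generate_cohort(cfg, null_effects())
  tab <- b$exposome
  subs <- build_subsets(tab, list(
    all = character(0),
    small = "null_01",
    wide = c("null_01", "null_02", "null_03")))
  expect_identical(subs$all, tab$id)
  expect_true(all(subs$wide %in% subs$small))
  gtm <- b$ground_truth$missing_blocks
  expect_identical(sort(subs$small), sort(setdiff(tab$id, gtm$A)))
  expect_identical(sort(subs$wide),
                   sort(setdiff(tab$id, union(gtm$A, gtm$B))))
  expect_error(build_subsets(tab, list(x = "ghost")), "unknown variable")
})

test_that("redundancy matrix is symmetric with unit diagonal and near-zero off-diagonals for independent draws", {
  set.seed(8)
  tab <- data.frame(id = paste0("p", 1:5000),
                    matrix(rnorm(5000 * 6), 5000, 6))
  cm <- redundancy_heatmap(tab)
  expect_identical(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.05)

  tab$dup <- tab$X1
  cm2 <- redundancy_heatmap(tab)
  expect_equal(cm2["X1", "dup"], 1, tolerance = 1e-12)

  tab$flat <- 1
  cm3 <- redundancy_heatmap(tab)
  expect_true(all(is.na(cm3["flat", setdiff(colnames(cm3), "flat")])))
  expect_identical(attr(cm3, "zero_variance"), "flat")
  expect_error(redundancy_heatmap(tab[, 1:2]), "at least 2")
})

test_that("the full curation chain is idempotent, never imputes, and its report reconciles with cell diffs", {
  b <- generate_cohort(cohort_config(n_participants = 400, n_regions = 10,
                                     granularity_levels = 10, seed = 21))
  parts <- b$participants
  c1 <- curate_exposome(b$exposome, b$specs, parts, n_min = 5)
  c2 <- curate_exposome(c1$table, c1$specs, parts, n_min = 5)
  strip <- function(d) {
    attr(d, "curation_log") <- NULL
    d
  }
  expect_equal(strip(c2$table), strip(c1$table))

  # non-missing cell count never increases except through new duration columns
  shared <- intersect(names(b$exposome), names(c1$table))
  before <- sum(!is.na(b$exposome[, shared]))
  after <- sum(!is.na(c1$table[, shared]))
  expect_lte(after, before)

  # nulled-cell counts reconcile exactly with the report
  rep <- c1$report
  nulled <- sum(rep$count[rep$step %in% c("aberrant", "uninformative")])
  expect_identical(before - after, as.integer(nulled))

  # the injected uninformative/aberrant cells are the ones found
  inj <- b$ground_truth$injected
  for (v in names(inj$uninformative)) {
    expect_identical(sum(rep$count[rep$step == "uninformative" &
                                     rep$variable == v]),
                     inj$uninformative[[v]])
  }
  for (v in names(inj$aberrant)) {
    # range validation runs once before and once after duration derivation;
    # the second pass finds nothing new
    expect_identical(sum(rep$count[rep$step == "aberrant" &
                                     rep$variable == v]),
                     inj$aberrant[[v]])
  }
})
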