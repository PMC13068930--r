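#' Assign cross-validation folds
#'
#' @param n number of rows.
#' @param k number of folds (`>= 2`).
#' @param seed integer seed; fold assignment is a pure function of
#'   `(n, k, seed, strata)`.
#' @param strata optional vector of length `n`; folds are balanced within
#'   each stratum.
#' @return integer vector of fold ids in `1:k`.
#' @export
make_folds <- function(n, k, seed = 1, strata = NULL) {
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  folds <- integer(n)
  if (is.null(strata)) strata <- rep(1L, n)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

#' Stratified holdout split
#'
#' Splits rows into a training and a held-out set, stratified so each
#' stratum contributes (close to) the same held-out fraction.
#'
#' @param n number of rows.
#' @param fraction held-out fraction in (0, 1).
#' @param seed integer seed.
#' @param strata optional stratification vector (e.g. age deciles).
#' @return list with integer vectors `train` and `holdout`.
#' @export
holdout_split <- function(n, fraction, seed = 1, strata = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  if (is.null(strata)) strata <- rep(1L, n)
  hold <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    m <- round(length(idx) * fraction)
    if (m > 0) hold <- c(hold, sample(idx, m))
  }
  hold <- sort(hold)
  list(train = setdiff(seq_len(n), hold), holdout = hold)
}
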