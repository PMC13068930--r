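#' @useDynLib expobag, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef cor lm.fit median predict quantile rbinom rnorm
#'   runif sd var p.adjust complete.cases setNames
#' @importFrom utils read.csv write.csv head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible substream seed
#'
#' A single user-facing integer seed is expanded into per-component
#' substreams with a fixed multiplicative recurrence, so that each table or
#' stage of a run draws from its own reproducible stream and stays below
#' the 32-bit integer ceiling.
#'
#' @param seed base integer seed.
#' @param k substream index (0, 1, 2, ...).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, k) {
  stopifnot(length(seed) == 1, is.finite(seed), length(k) == 1, k >= 0)
  m <- 2147483647          # 2^31 - 1 (Mersenne prime modulus)
  s <- (abs(as.numeric(seed)) %% (m - 1)) + 1
  for (i in seq_len(k + 1)) s <- (s * 48271) %% m
  as.integer(s)
}

.assert_numeric_matrix <- function(X, what = "X") {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix or data frame", what), call. = FALSE)
  }
  X
}

.stop_schema <- function(...) stop(..., call. = FALSE)
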