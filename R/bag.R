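# Age-bias correction and the Brain Age Gap. Brain-age predictions are
# systematically biased toward the sample mean (over-predicted at young
# ages, under-predicted at old ages); regressing predicted age on
# chronological age in the training set and inverting that line removes
# the artefactual correlation between the gap and age.

#' Fit the age-bias correction
#'
#' Ordinary least squares of predicted age on chronological age, estimated
#' on training data only. The fitted slope and intercept are later inverted
#' by [apply_correction()].
#'
#' @param predicted predicted ages (years).
#' @param chronological chronological ages (years), same length (`>= 3`).
#' @param source optional label of the training set the parameters come from.
#' @return an object of class `bias_correction` with `slope`, `intercept`,
#'   `source` and `n`.
#' @export
fit_bias_correction <- function(predicted, chronological, source = NULL) {
  stopifnot(length(predicted) == length(chronological),
            length(predicted) >= 3)
  if (anyNA(predicted) || anyNA(chronological)) {
    stop("missing values in inputs", call. = FALSE)
  }
  if (var(chronological) == 0) {
    stop("chronological age has zero variance", call. = FALSE)
  }
  slope <- cov(predicted, chronological) / var(chronological)
  intercept <- mean(predicted) - slope * mean(chronological)
  if (abs(slope) < 1e-6) {
    stop("degenerate model: |slope| < 1e-6, the prediction carries no age ",
         "signal", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept, source = source,
                 n = length(predicted)),
            class = "bias_correction")
}

#' Apply the age-bias correction
#'
#' `adjusted = (predicted - intercept) / slope`.
#'
#' @param predicted predicted ages (years).
#' @param params a [fit_bias_correction()] result.
#' @return adjusted predicted ages (years).
#' @export
apply_correction <- function(predicted, params) {
  stopifnot(inherits(params, "bias_correction"))
  (predicted - params$intercept) / params$slope
}

#' Compute the Brain Age Gap table
#'
#' BAG is the adjusted predicted age minus the chronological age: positive
#' values flag a brain appearing older than its chronological age, negative
#' values a relatively preserved one. Summary statistics (mean, SD, 5th and
#' 95th percentiles) are attached.
#'
#' @param adjusted adjusted predicted ages (years).
#' @param chronological chronological ages (years), same length.
#' @param id optional participant ids.
#' @param raw optional raw (uncorrected) predicted ages, echoed in the table.
#' @return a data frame of class `bag_table` with columns `id`, `age`,
#'   `predicted_raw`, `predicted_adjusted`, `bag`, and a `summary` attribute.
#' @export
compute_bag <- function(adjusted, chronological, id = NULL, raw = NULL) {
  stopifnot(length(adjusted) == length(chronological))
  if (any(!is.finite(adjusted)) || any(!is.finite(chronological))) {
    stop("non-finite values in inputs", call. = FALSE)
  }
  bag <- adjusted - chronological
  out <- data.frame(
    id = id %||% seq_along(bag),
    age = chronological,
    predicted_raw = raw %||% rep(NA_real_, length(bag)),
    predicted_adjusted = adjusted,
    bag = bag)
  attr(out, "summary") <- c(
    mean = mean(bag), sd = sd(bag),
    q05 = unname(quantile(bag, 0.05)), q95 = unname(quantile(bag, 0.95)))
  class(out) <- c("bag_table", "data.frame")
  out
}

#' @export
print.bag_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("Brain Age Gap, n = %d: mean %.3f y, sd %.3f y, 5th/95th pct %.2f / %.2f y\n",
              nrow(x), s["mean"], s["sd"], s["q05"], s["q95"]))
  invisible(x)
}
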