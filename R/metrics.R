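#' Root mean square error
#'
#' `RMSE = sqrt(sum((p - o)^2) / n)`, in the units of the inputs (mg/g for
#' yield curves).
#'
#' @param predicted,observed Equal-length finite numeric vectors.
#' @return RMSE, scalar.
#' @export
rmse <- function(predicted, observed) {
  check_metric_args(predicted, observed)
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about the
#' observed mean. Can be negative for models worse than the mean; errors when
#' the observations are all equal (SS_tot = 0, undefined).
#'
#' @inheritParams rmse
#' @return R^2, scalar (<= 1).
#' @export
r_squared <- function(predicted, observed) {
  check_metric_args(predicted, observed)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: observations are all equal (zero total sum of squares)",
         call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Absolute average deviation (percent)
#'
#' `AAD% = 100 / n * sum(|o - p| / o)`. Requires strictly positive
#' observations.
#'
#' @inheritParams rmse
#' @return AAD in percent.
#' @export
aad <- function(predicted, observed) {
  check_metric_args(predicted, observed)
  if (any(observed <= 0)) {
    stop("AAD undefined: all observed values must be > 0", call. = FALSE)
  }
  100 * mean(abs(observed - predicted) / observed)
}

check_metric_args <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("`predicted` and `observed` must have equal length", call. = FALSE)
  }
  if (length(predicted) == 0L) stop("empty input", call. = FALSE)
  if (!all(is.finite(predicted)) || !all(is.finite(observed))) {
    stop("inputs must be finite", call. = FALSE)
  }
  invisible(TRUE)
}
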