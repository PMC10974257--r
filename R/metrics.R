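#' Pearson correlation between a signal and its estimate
#'
#' The product-moment correlation of the two demeaned traces; invariant to
#' affine rescaling with positive slope of either argument.
#'
#' @param x,y_hat Equal-length numeric vectors, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(x, y_hat) {
  if (length(x) != length(y_hat)) stop_data("length mismatch")
  if (length(x) < 2) stop_data("need at least two samples")
  if (sd(x) == 0 || sd(y_hat) == 0)
    stop_data("correlation undefined for a constant input")
  cor(x, y_hat)
}

#' Root-mean-square error
#' @param y_hat Estimate.
#' @param y Reference, same length.
#' @return Non-negative scalar.
#' @export
rmse <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop_data("length mismatch")
  sqrt(mean((y_hat - y)^2))
}

#' Mean absolute error
#' @param y_hat Estimate.
#' @param y Reference, same length.
#' @return Non-negative scalar; never exceeds the RMSE of the same pair.
#' @export
mae <- function(y_hat, y) {
  if (length(y_hat) != length(y)) stop_data("length mismatch")
  mean(abs(y_hat - y))
}

#' Contrast-to-noise ratio of a task/rest segmentation
#'
#' `(mean(task) - mean(rest)) / sqrt(var(task) + var(rest))` with population
#' (1/N) variances and segments pooled by concatenation.  Translation of the
#' whole trace leaves the value unchanged; a high CNR indicates a strong
#' task-locked contrast relative to within-state variability.
#'
#' @param task_segments,rest_segments Numeric vectors or lists of sample
#'   windows (pooled by concatenation); each pooled segment needs >= 2 samples.
#' @return Scalar CNR.
#' @export
cnr <- function(task_segments, rest_segments) {
  task <- unlist(task_segments, use.names = FALSE)
  rest <- unlist(rest_segments, use.names = FALSE)
  if (length(task) < 2 || length(rest) < 2)
    stop_data("each pooled segment needs at least 2 samples")
  varp <- function(z) mean((z - mean(z))^2)
  denom <- varp(task) + varp(rest)
  if (denom == 0) stop_data("zero pooled variance; CNR undefined")
  (mean(task) - mean(rest)) / sqrt(denom)
}

#' Normalize a trace for comparison
#'
#' Removes the mean and divides by the maximum absolute deviation
#' (`"maxabs"`, the convention used for benchmark scoring) or the standard
#' deviation (`"zscore"`).
#'
#' @param x Numeric vector.
#' @param scheme `"maxabs"` or `"zscore"`.
#' @return Normalized vector; a constant input returns all zeros.
#' @export
normalize_trace <- function(x, scheme = c("maxabs", "zscore")) {
  scheme <- match.arg(scheme)
  xc <- x - mean(x)
  s <- if (scheme == "maxabs") max(abs(xc)) else sd(x)
  if (s == 0) return(xc)
  xc / s
}

#' Score an estimate against ground truth
#'
#' Normalizes both traces with [normalize_trace()] and reports the Pearson
#' correlation, RMSE and MAE in one object.
#'
#' @param estimate,truth Equal-length traces.
#' @param scheme Normalization passed to [normalize_trace()].
#' @return An object of class `metric_report`: `r`, `rmse`, `mae`, `n`.
#' @export
compare_traces <- function(estimate, truth, scheme = "maxabs") {
  ne <- normalize_trace(estimate, scheme)
  nt <- normalize_trace(truth, scheme)
  structure(list(r = pearson_r(nt, ne), rmse = rmse(ne, nt),
                 mae = mae(ne, nt), n = length(ne)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("R = %.5f, RMSE = %.5f, MAE = %.5f (n = %d)\n",
              x$r, x$rmse, x$mae, x$n))
  invisible(x)
}
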