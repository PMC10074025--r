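#' Normalized root-mean-square error
#'
#' NRMSE divides the RMSE of the predictions by the RMSE of the constant
#' mean predictor, both evaluated on the same set:
#' \deqn{\mathrm{NRMSE} = \sqrt{\sum_j (y_j-\hat y_j)^2} \big/
#'       \sqrt{\sum_j (y_j-\bar y)^2}}
#' where \eqn{\bar y} is the mean of the evaluation set's own targets, so
#' that predicting the mean scores exactly 1 and a perfect fit scores 0.
#'
#' @param y numeric vector of observed targets (length >= 2, non-constant).
#' @param yhat numeric vector of predictions, same length as \code{y}.
#' @return non-negative scalar.
#' @examples
#' nrmse(c(1, 2, 3), c(1, 2, 4))      # sqrt(0.5)
#' nrmse(c(1, 2, 3), rep(2, 3))       # mean predictor -> 1
#' @export
nrmse <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop_input("y and yhat must have equal length")
  if (length(y) < 2) stop_input("need at least 2 observations")
  if (!all(is.finite(y)) || !all(is.finite(yhat)))
    stop_input("non-finite values in y or yhat")
  denom <- sum((y - mean(y))^2)
  if (denom <= 0) stop_input("targets are constant: NRMSE denominator is zero")
  sqrt(sum((y - yhat)^2)) / sqrt(denom)
}

#' Pearson correlation between predictions and targets
#'
#' @param y numeric vector of observed targets.
#' @param yhat numeric vector of predictions.
#' @return scalar in \eqn{[-1, 1]}.
#' @export
pcc <- function(y, yhat) {
  y <- as.numeric(y); yhat <- as.numeric(yhat)
  if (length(y) != length(yhat)) stop_input("y and yhat must have equal length")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop_input("PCC undefined for a constant vector")
  stats::cor(y, yhat)
}

#' Average metric rows over replicate data splits
#'
#' Collapses a per-replicate metric table (as emitted by
#' \code{\link{run_experiment}}) to means over replicates, the reporting
#' convention used for multi-split simulation studies.
#'
#' @param report data.frame with columns \code{model}, \code{setting},
#'   \code{replicate}, \code{nrmse}, \code{pcc} (extra columns are dropped).
#' @return data.frame with one row per (model, setting) and mean metrics.
#' @export
average_replicates <- function(report) {
  stopifnot(is.data.frame(report))
  need <- c("model", "setting", "nrmse", "pcc")
  if (!all(need %in% names(report)))
    stop_input("report must contain columns: %s", paste(need, collapse = ", "))
  agg <- stats::aggregate(report[c("nrmse", "pcc")],
                          by = report[c("model", "setting")], FUN = mean)
  agg[order(agg$model, agg$setting), , drop = FALSE]
}
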