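# Gelman-Rubin style diagnostic on per-client validation-loss trajectories.
# Homogeneous clients produce well-mixed trajectories (R near 1); clients
# observing distinct population clusters produce trajectories with large
# between-client variance (R >> 1).

#' Between- and within-trajectory variance of client loss trajectories
#'
#' Given per-client validation-loss trajectories
#' \eqn{x_1^{(j)},\dots,x_{m-1}^{(j)}} observed up to the convergence point
#' m, computes the client means \eqn{\bar x_j}, the grand mean
#' \eqn{\bar x}, the between-trajectory variance
#' \eqn{B = \frac{m-1}{n-1}\sum_j(\bar x_j - \bar x)^2}, the
#' within-trajectory variances
#' \eqn{W_j = \frac{1}{m-2}\sum_t (x_t^{(j)} - \bar x_j)^2} and their mean
#' \eqn{W}, plus the mixing weight \eqn{\alpha = 1/(m-1)}.
#'
#' @param trajectories list of numeric vectors (one per client), a numeric
#'   matrix with one column per client, or a federation round-log
#'   data.frame with columns \code{round}, \code{client} (or
#'   \code{client_id}) and \code{val_nrmse}.
#' @param m convergence round; trajectories are truncated to the first
#'   \code{m - 1} entries. Default: one more than the shortest trajectory.
#'   Requires \code{m >= 3}.
#' @return object of class \code{"trajectory_diag"} with fields
#'   \code{trajectories}, \code{client_means}, \code{grand_mean}, \code{B},
#'   \code{W_j}, \code{W}, \code{alpha}, \code{m}, \code{n}.
#' @export
trajectory_stats <- function(trajectories, m = NULL) {
  if (is.data.frame(trajectories)) {
    cl <- trajectories$client %||% trajectories$client_id
    trajectories <- lapply(split(trajectories, cl), function(d)
      d$val_nrmse[order(d$round)])
  }
  if (is.matrix(trajectories))
    trajectories <- lapply(seq_len(ncol(trajectories)),
                           function(j) trajectories[, j])
  n <- length(trajectories)
  if (n < 2L) stop_input("need at least 2 client trajectories")
  lens <- lengths(trajectories)
  if (length(unique(lens)) > 1L) {
    warning("ragged trajectories: truncating to the shortest")
  }
  len <- min(lens)
  m <- as.integer(m %||% (len + 1L))
  if (m < 3L) stop_input("m must be >= 3 (within-variance divides by m - 2)")
  if (m - 1L > len)
    stop_input("m = %d needs trajectories of length %d; shortest is %d",
               m, m - 1L, len)
  X <- vapply(trajectories, function(v) v[seq_len(m - 1L)], numeric(m - 1L))
  xbar_j <- colMeans(X)
  xbar <- mean(xbar_j)
  B <- (m - 1) / (n - 1) * sum((xbar_j - xbar)^2)
  W_j <- colSums((X - matrix(xbar_j, m - 1L, n, byrow = TRUE))^2) / (m - 2)
  structure(list(trajectories = X, client_means = xbar_j, grand_mean = xbar,
                 B = B, W_j = W_j, W = mean(W_j), alpha = 1 / (m - 1),
                 m = m, n = n),
            class = "trajectory_diag")
}

#' Mixing statistic R from trajectory variances
#'
#' \deqn{R = \frac{\alpha B + (1-\alpha) W}{W}, \quad \alpha = 1/(m-1).}
#' As \eqn{B \to 0} and m grows, \eqn{R \to 1} (well-mixed, homogeneous
#' clients); \eqn{R \gg 1} indicates clients observing heterogeneous
#' population clusters. R is invariant to rescaling the losses.
#'
#' @param diag a \code{\link{trajectory_stats}} result.
#' @return scalar R; \code{Inf} (with a message) when \eqn{W = 0} but
#'   \eqn{B > 0}; \code{NaN} when both are 0.
#' @export
r_statistic <- function(diag) {
  stopifnot(inherits(diag, "trajectory_diag"))
  a <- diag$alpha
  if (diag$W <= 0) {
    if (diag$B > 0) {
      message("within-trajectory variance is zero with positive between-variance: R = Inf")
      return(Inf)
    }
    return(NaN)
  }
  (a * diag$B + (1 - a) * diag$W) / diag$W
}

#' Flag client heterogeneity from R
#'
#' @param R the mixing statistic.
#' @param threshold decision cutoff (default 1.5, a tool default).
#' @return logical flag: \code{TRUE} when \code{R > threshold}.
#' @export
detect_heterogeneity <- function(R, threshold = 1.5) {
  if (!is.finite(R) && is.nan(R)) stop_input("R is undefined (NaN)")
  isTRUE(R > threshold)
}

#' One-call heterogeneity report for a federation
#'
#' Computes trajectory statistics and R from a fitted
#' \code{\link{run_federation}} object (or a round-log data.frame) and
#' returns the JSON-ready report list.
#'
#' @param fed a \code{"federation"} or a round-log data.frame.
#' @param m convergence round (default: all recorded rounds).
#' @param threshold heterogeneity cutoff.
#' @return object of class \code{"heterogeneity_report"}: list(B, W, alpha,
#'   m, n, R, flag).
#' @export
diagnose_heterogeneity <- function(fed, m = NULL, threshold = 1.5) {
  h <- if (inherits(fed, "federation")) fed$history else fed
  ts <- trajectory_stats(h, m = m)
  R <- r_statistic(ts)
  structure(list(B = ts$B, W = ts$W, alpha = ts$alpha, m = ts$m, n = ts$n,
                 R = R, flag = detect_heterogeneity(R, threshold),
                 threshold = threshold, stats = ts),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("Client heterogeneity diagnostic (n = %d clients, m = %d)\n",
              x$n, x$m))
  cat(sprintf("  between-trajectory variance B = %.6g\n", x$B))
  cat(sprintf("  mean within-trajectory variance W = %.6g\n", x$W))
  cat(sprintf("  R = %.4f (threshold %.2f) -> %s\n", x$R, x$threshold,
              if (x$flag) "heterogeneous clusters indicated" else "well mixed"))
  invisible(x)
}

#' @export
print.trajectory_diag <- function(x, ...) {
  cat(sprintf("Loss trajectories: %d clients x %d rounds (m = %d)\n",
              x$n, nrow(x$trajectories), x$m))
  cat(sprintf("B = %.6g, W = %.6g, alpha = %.4f\n", x$B, x$W, x$alpha))
  invisible(x)
}

#' Write a heterogeneity report as JSON
#'
#' @param report a \code{\link{diagnose_heterogeneity}} result.
#' @param path output file.
#' @export
write_heterogeneity_report <- function(report, path) {
  stopifnot(inherits(report, "heterogeneity_report"))
  jsonlite::write_json(report[c("B", "W", "alpha", "m", "n", "R", "flag")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
plot.trajectory_diag <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$trajectories)), x$trajectories, type = "l",
                    lty = 1, xlab = "round", ylab = "validation loss",
                    main = "Per-client loss trajectories", ...)
  invisible(x)
}
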