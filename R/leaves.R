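#' Initialize Gaussian leaf distributions
#'
#' Every leaf starts from a Normal(1, 1) prediction distribution: all leaf
#' means are 1 and all leaf variances are 1 (the scalar-response reduction of
#' a Normal(1, I) initialization).
#'
#' @param topo a \code{\link{tree_topology}}.
#' @param n_trees number of trees in the forest.
#' @return list of class \code{"drf_leaves"}: \code{mu} and \code{s2},
#'   each an \code{n_trees x n_leaves} matrix.
#' @export
init_leaves <- function(topo, n_trees) {
  stopifnot(inherits(topo, "tree_topology"))
  n_trees <- as.integer(n_trees)
  if (n_trees < 1L) stop_input("n_trees must be >= 1")
  structure(list(mu = matrix(1, n_trees, topo$n_leaves),
                 s2 = matrix(1, n_trees, topo$n_leaves)),
            class = "drf_leaves")
}

#' Prediction of a single tree
#'
#' The tree prediction is the expectation of the leaf means under the
#' routing distribution: \eqn{\sum_\ell P(\ell|x)\,\mu_\ell}.
#'
#' @param P numeric vector of leaf arrival probabilities (or matrix, one row
#'   per sample).
#' @param mu numeric vector of leaf means, same number of leaves.
#' @return scalar (or vector with one entry per sample).
#' @export
tree_predict <- function(P, mu) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
  if (ncol(P) != length(mu))
    stop_input("leaf probability and leaf mean dimensions disagree (%d vs %d)",
               ncol(P), length(mu))
  drop(P %*% mu)
}

#' Prediction of a forest
#'
#' @param tree_preds numeric vector (or matrix, one column per tree) of
#'   per-tree predictions.
#' @return arithmetic mean over trees.
#' @export
forest_predict <- function(tree_preds) {
  if (is.null(dim(tree_preds))) {
    if (length(tree_preds) < 1L) stop_input("empty forest")
    return(mean(tree_preds))
  }
  if (ncol(tree_preds) < 1L) stop_input("empty forest")
  rowMeans(tree_preds)
}

# log N(y; mu, s2) for a vector y against leaf vectors -> n x L matrix
log_gauss <- function(y, mu, s2) {
  n <- length(y); L <- length(mu)
  M <- matrix(mu, n, L, byrow = TRUE)
  V <- matrix(s2, n, L, byrow = TRUE)
  -0.5 * log(2 * pi * V) - (y - M)^2 / (2 * V)
}

#' Negative log-likelihood of the deep regression forest
#'
#' The per-sample loss of one tree is the negative log of the Gaussian
#' mixture whose weights are the routing probabilities:
#' \eqn{-\log \sum_\ell P(\ell|x)\, N(y;\mu_\ell,\sigma^2_\ell)}. The forest
#' loss averages over trees and over the batch. Computed through
#' log-sum-exp so that underflowing mixtures never produce NaN.
#'
#' @param y numeric vector of targets.
#' @param P leaf probabilities: an \code{n x n_leaves} matrix (single tree)
#'   or a list of such matrices, one per tree.
#' @param leaves a \code{\link{init_leaves}} object (rows indexed by tree).
#' @return scalar mean negative log-likelihood.
#' @export
drf_nll <- function(y, P, leaves) {
  stopifnot(inherits(leaves, "drf_leaves"))
  Plist <- if (is.list(P)) P else list(P)
  n_trees <- nrow(leaves$mu)
  if (length(Plist) != n_trees)
    stop_input("got %d routing matrices for %d trees", length(Plist), n_trees)
  total <- 0
  for (t in seq_len(n_trees)) {
    Pt <- Plist[[t]]
    if (is.null(dim(Pt))) Pt <- matrix(Pt, nrow = length(y), byrow = TRUE)
    lg <- log_gauss(y, leaves$mu[t, ], leaves$s2[t, ])
    # log sum_l exp(log P + log N); guard log(0) with -Inf, handled by max-shift
    lp <- log(Pt)
    a <- lp + lg
    m <- apply(a, 1L, max)
    m[!is.finite(m)] <- 0   # all-zero mixture row: density 0 -> large finite loss
    ll <- m + log(rowSums(exp(a - m)))
    ll[!is.finite(ll)] <- -745  # ~ log(double eps underflow), never NaN
    total <- total + mean(-ll)
  }
  total / n_trees
}

#' Update Gaussian leaf parameters by variational bounding
#'
#' With the network (and hence the routing probabilities) held fixed, the
#' leaf means and variances of each tree are updated by alternating
#' closed-form steps: posterior responsibilities
#' \eqn{\xi_{i\ell} \propto P(\ell|x_i)\, N(y_i;\mu_\ell,\sigma^2_\ell)}
#' (rows normalized), then responsibility-weighted mean and variance per
#' leaf. Each iteration is an EM step on the per-tree mixture likelihood,
#' so the training-batch NLL is non-increasing across iterations. Leaves
#' whose total responsibility falls below 1e-12 keep their previous
#' parameters; variances are floored at \code{variance_floor}.
#'
#' @param y numeric vector of targets (non-empty).
#' @param P routing matrix or list of per-tree routing matrices (as in
#'   \code{\link{drf_nll}}).
#' @param leaves current \code{"drf_leaves"}.
#' @param n_iter number of update iterations (default 3).
#' @param variance_floor lower bound for leaf variances (default 1e-4).
#' @return updated \code{"drf_leaves"} object.
#' @export
update_leaves <- function(y, P, leaves, n_iter = 3L, variance_floor = 1e-4) {
  stopifnot(inherits(leaves, "drf_leaves"))
  if (length(y) < 1L) stop_input("empty batch")
  Plist <- if (is.list(P)) P else list(P)
  n_trees <- nrow(leaves$mu)
  if (length(Plist) != n_trees)
    stop_input("got %d routing matrices for %d trees", length(Plist), n_trees)
  mu <- leaves$mu; s2 <- leaves$s2
  for (t in seq_len(n_trees)) {
    Pt <- Plist[[t]]
    if (is.null(dim(Pt))) Pt <- matrix(Pt, nrow = length(y), byrow = TRUE)
    for (it in seq_len(n_iter)) {
      xi <- responsibilities(y, Pt, mu[t, ], s2[t, ])
      tot <- colSums(xi)
      act <- tot > 1e-12
      if (!any(act)) break
      mu_new <- mu[t, ]
      mu_new[act] <- colSums(xi[, act, drop = FALSE] * y) / tot[act]
      s2_new <- s2[t, ]
      dev2 <- (matrix(y, length(y), sum(act)) -
                 matrix(mu_new[act], length(y), sum(act), byrow = TRUE))^2
      s2_new[act] <- pmax(variance_floor,
                          colSums(xi[, act, drop = FALSE] * dev2) / tot[act])
      mu[t, ] <- mu_new
      s2[t, ] <- s2_new
    }
  }
  structure(list(mu = mu, s2 = s2), class = "drf_leaves")
}

# posterior weight of sample i at leaf l; rows normalized to sum 1
responsibilities <- function(y, P, mu, s2) {
  a <- log(P) + log_gauss(y, mu, s2)
  m <- apply(a, 1L, max)
  bad <- !is.finite(m)
  m[bad] <- 0
  xi <- exp(a - m)
  rs <- rowSums(xi)
  rs[rs <= 0] <- 1
  xi <- xi / rs
  # fully underflowed rows fall back to the routing prior
  if (any(bad)) xi[bad, ] <- P[bad, , drop = FALSE]
  xi
}
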