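#' Fixed binary-tree topology for a regression forest
#'
#' Trees are full binary trees of the given depth with nodes in breadth-first
#' (heap) order, root first: internal nodes are heap indices
#' \code{1..2^(depth-1)-1} and leaves \code{2^(depth-1)..2^depth-1}. A forest
#' of \code{T} trees consumes \code{T * n_internal} sigmoid routing outputs
#' from the network head, sliced contiguously per tree.
#'
#' @param depth tree depth, an integer >= 2 (depth 3 gives 3 internal nodes
#'   and 4 leaves).
#' @return object of class \code{"tree_topology"} with elements
#'   \code{depth}, \code{n_internal}, \code{n_leaves}, and the path matrices
#'   \code{left}/\code{right} (\code{n_leaves x n_internal} 0/1 indicators of
#'   which internal nodes are crossed leftwards/rightwards on the root-to-leaf
#'   path).
#' @export
tree_topology <- function(depth) {
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 2L)
    stop_input("depth must be a single integer >= 2")
  n_internal <- 2L^(depth - 1L) - 1L
  n_leaves <- 2L^(depth - 1L)
  left <- matrix(0L, n_leaves, n_internal)
  right <- matrix(0L, n_leaves, n_internal)
  for (l in seq_len(n_leaves)) {
    h <- n_internal + l          # heap index of this leaf
    while (h > 1L) {
      parent <- h %/% 2L
      if (h %% 2L == 0L) left[l, parent] <- 1L else right[l, parent] <- 1L
      h <- parent
    }
  }
  structure(list(depth = depth, n_internal = n_internal, n_leaves = n_leaves,
                 left = left, right = right),
            class = "tree_topology")
}

#' @export
print.tree_topology <- function(x, ...) {
  cat(sprintf("Binary tree topology: depth %d, %d internal nodes, %d leaves\n",
              x$depth, x$n_internal, x$n_leaves))
  invisible(x)
}

#' Soft routing probabilities of reaching each leaf
#'
#' Each internal node carries a left-branch probability \code{s} (a sigmoid
#' of a network output); the probability of a sample arriving at a leaf is
#' the product over its root-to-leaf path of \code{s} at nodes crossed
#' leftwards and \code{1 - s} at nodes crossed rightwards. The leaf
#' probabilities always sum to 1.
#'
#' @param s numeric vector of left-branch probabilities in \eqn{[0,1]}, one
#'   per internal node in breadth-first order, or a matrix with one row per
#'   sample.
#' @param topo a \code{\link{tree_topology}}.
#' @return numeric vector (or matrix, one row per sample) of length
#'   \code{topo$n_leaves}.
#' @examples
#' topo <- tree_topology(3)
#' routing_probabilities(c(0.8, 0.6, 0.3), topo)  # 0.48 0.32 0.06 0.14
#' @export
routing_probabilities <- function(s, topo) {
  stopifnot(inherits(topo, "tree_topology"))
  vec <- is.null(dim(s))
  S <- if (vec) matrix(as.numeric(s), nrow = 1L) else as.matrix(s)
  if (ncol(S) != topo$n_internal)
    stop_input("expected %d routing entries, got %d", topo$n_internal, ncol(S))
  if (anyNA(S) || any(S < 0) || any(S > 1))
    stop_input("routing probabilities must lie in [0, 1]")
  P <- matrix(1, nrow(S), topo$n_leaves)
  for (k in seq_len(topo$n_internal)) {
    lv <- which(topo$left[, k] == 1L)
    rv <- which(topo$right[, k] == 1L)
    P[, lv] <- P[, lv, drop = FALSE] * S[, k]
    P[, rv] <- P[, rv, drop = FALSE] * (1 - S[, k])
  }
  if (vec) drop(P) else P
}
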