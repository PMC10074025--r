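# Feature-to-image embedding: place each of p features on a g x g pixel
# grid so that features that co-vary strongly in the data end up as
# neighbouring pixels, making the resulting per-sample images amenable to
# convolutional feature extraction.

#' Pairwise distance between features
#'
#' Columns are standardized to zero mean and unit (population) variance,
#' constant columns mapping to all-zero, and the distance between features
#' i and j is the Euclidean distance between their standardized columns
#' scaled by \eqn{1/\sqrt{n}}:
#' \eqn{d_{ij} = \sqrt{\sum_k (z_{ki} - z_{kj})^2 / n}}. With
#' \code{metric = "correlation"}, \eqn{d_{ij} = 1 - |r_{ij}|} is used
#' instead (constant columns get r = 0).
#'
#' @param X numeric matrix, rows = samples (>= 2), columns = features (>= 2).
#' @param metric \code{"euclidean"} (default) or \code{"correlation"}.
#' @return object of class \code{"feature_distance"}: list with the
#'   symmetric zero-diagonal \code{matrix} and \code{feature_names}.
#' @export
feature_distance_matrix <- function(X, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  X <- check_numeric_matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop_input("need at least 2 samples")
  if (p < 2L) stop_input("need at least 2 features")
  nms <- colnames(X) %||% paste0("f", seq_len(p))
  if (metric == "euclidean") {
    mu <- colMeans(X)
    sdev <- sqrt(colMeans(X^2) - mu^2)          # population sd
    Z <- sweep(X, 2L, mu)
    ok <- sdev > 0
    Z[, ok] <- sweep(Z[, ok, drop = FALSE], 2L, sdev[ok], "/")
    Z[, !ok] <- 0
    D <- as.matrix(stats::dist(t(Z))) / sqrt(n)
  } else {
    R <- suppressWarnings(stats::cor(X))
    R[!is.finite(R)] <- 0
    D <- 1 - abs(R)
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(nms, nms)
  structure(list(matrix = D, feature_names = nms), class = "feature_distance")
}

#' Initial 2D embedding of the features by metric MDS
#'
#' Classical multidimensional scaling of the feature-distance matrix,
#' rescaled so the coordinates span \eqn{[0, g-1]^2}. Axis signs are
#' canonicalized (largest-magnitude coordinate positive), so the embedding
#' is fully deterministic.
#'
#' @param d a \code{\link{feature_distance_matrix}} result.
#' @param grid_side side length g of the target grid.
#' @return p x 2 matrix of coordinates.
#' @export
initial_embedding <- function(d, grid_side) {
  stopifnot(inherits(d, "feature_distance"))
  g <- as.integer(grid_side)
  if (g < 1L) stop_input("grid_side must be positive")
  D <- d$matrix
  p <- nrow(D)
  if (all(D == 0)) {
    warning("degenerate all-zero distance matrix: placing all features at the grid center")
    ctr <- (g - 1) / 2
    return(matrix(ctr, p, 2L, dimnames = list(d$feature_names, NULL)))
  }
  co <- suppressWarnings(stats::cmdscale(D, k = min(2L, p - 1L)))
  if (ncol(co) < 2L) co <- cbind(co, 0)
  # canonical axis orientation for determinism
  for (j in 1:2) {
    i <- which.max(abs(co[, j]))
    if (length(i) && co[i, j] < 0) co[, j] <- -co[, j]
  }
  # rescale to span [0, g-1]^2 preserving the aspect ratio
  rng <- max(apply(co, 2L, function(v) diff(range(v))))
  if (rng > 0) co <- (co - matrix(apply(co, 2L, min), p, 2L, byrow = TRUE)) *
      (g - 1) / rng
  rownames(co) <- d$feature_names
  co
}

grid_cells <- function(g) {
  cbind(row = rep(seq_len(g), each = g), col = rep(seq_len(g), g))
}

# total embedding stress of an assignment: sum_{i<j} (d_ij - grid_dist_ij)^2
assignment_stress <- function(D, cells, assign_idx) {
  xy <- cells[assign_idx, , drop = FALSE]
  gd <- as.matrix(stats::dist(xy))
  sum((D[upper.tri(D)] - gd[upper.tri(gd)])^2)
}

#' Snap embedded features onto distinct grid cells and refine
#'
#' First pass: features (in ascending index order) are greedily snapped to
#' the nearest free grid cell, ties broken by lowest (row, col). Refinement:
#' repeated sweeps of pairwise-swap hill climbing — every feature is tried
#' against every other cell (swapping occupants, or moving into a free
#' cell), accepting only moves that strictly decrease the total stress
#' \eqn{\sum_{i<j}(d_{ij} - \mathrm{grid\_dist}_{ij})^2}. Stress is
#' therefore non-increasing; iteration stops after \code{max_iters} sweeps
#' or a sweep with no accepted move.
#'
#' @param coords p x 2 embedding coordinates (0-based grid units, as from
#'   \code{\link{initial_embedding}}).
#' @param d the \code{\link{feature_distance_matrix}} the embedding came from.
#' @param grid_side grid side g, requiring \eqn{p \le g^2}.
#' @param max_iters maximum refinement sweeps.
#' @param seed integer seed (randomizes the candidate sweep order and the
#'   restart configurations; the accept rule keeps every run a strict
#'   descent regardless).
#' @param restarts number of hill-climb runs: the first starts from the
#'   greedy snap of the MDS coordinates, the rest from seeded random
#'   placements, and the lowest-stress result is kept (so the final stress
#'   never exceeds the greedy initial stress). Default: 10 runs for
#'   p <= 12 features, 5 otherwise.
#' @return object of class \code{"refined_map"}: \code{assignment} (p x 2
#'   integer matrix of 1-based row/col), \code{grid_side}, \code{stress},
#'   \code{initial_stress}, \code{feature_names}.
#' @export
assign_pixels <- function(coords, d, grid_side, max_iters = 50L, seed = 1L,
                          restarts = NULL) {
  stopifnot(inherits(d, "feature_distance"))
  g <- as.integer(grid_side)
  p <- nrow(coords)
  # small instances are cheap to search and held to the tightest optimality
  # expectations, so they get more restarts by default
  restarts <- as.integer(restarts %||% if (p <= 12L) 10L else 5L)
  if (p > g * g) stop_input("grid capacity exceeded: %d features on a %dx%d grid", p, g, g)
  D <- d$matrix
  cells <- grid_cells(g)          # 1-based rows/cols
  xy0 <- cells - 1L               # cell centers in coordinate units
  # greedy snap, ascending feature index, nearest free cell,
  # ties -> lowest (row, col) lexicographic (the cells are generated in
  # that order, so which.min resolves ties correctly)
  free <- rep(TRUE, g * g)
  snap_idx <- integer(p)
  for (i in seq_len(p)) {
    d2 <- (xy0[, 1L] - coords[i, 1L])^2 + (xy0[, 2L] - coords[i, 2L])^2
    d2[!free] <- Inf
    cell <- which.min(d2)
    snap_idx[i] <- cell
    free[cell] <- FALSE
  }
  initial_stress <- assignment_stress(D, cells, snap_idx)
  celldist <- as.matrix(stats::dist(cells))
  # pairwise-swap hill climb (full 2-opt: occupied-occupied swaps and moves
  # into free cells), accepting only strict stress decreases
  climb <- function(assign_idx, run_seed) {
    occupant <- integer(g * g)    # 0 = free
    occupant[assign_idx] <- seq_len(p)
    contrib <- function(feat, cell, other_idx, other_feat) {
      sum((D[feat, other_feat] - celldist[cell, other_idx])^2)
    }
    for (sweep in seq_len(max_iters)) {
      moved <- FALSE
      order_feat <- with_seed(derive_seed(run_seed, sweep), sample.int(p))
      for (i in order_feat) {
        ci <- assign_idx[i]
        others <- setdiff(seq_len(p), i)
        base_i <- contrib(i, ci, assign_idx[others], others)
        for (cj in seq_len(g * g)) {
          if (cj == ci) next
          j <- occupant[cj]
          if (j == 0L) {
            delta <- contrib(i, cj, assign_idx[others], others) - base_i
          } else {
            oth2 <- setdiff(seq_len(p), c(i, j))
            a2 <- assign_idx[oth2]
            delta <- contrib(i, cj, a2, oth2) + contrib(j, ci, a2, oth2) -
              contrib(i, ci, a2, oth2) - contrib(j, cj, a2, oth2)
          }
          if (delta < -1e-12) {
            if (j == 0L) {
              occupant[ci] <- 0L
            } else {
              assign_idx[j] <- ci
              occupant[ci] <- j
            }
            assign_idx[i] <- cj
            occupant[cj] <- i
            ci <- cj
            others <- setdiff(seq_len(p), i)
            base_i <- contrib(i, ci, assign_idx[others], others)
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    assign_idx
  }
  best_idx <- climb(snap_idx, derive_seed(seed, 1L))
  best_stress <- assignment_stress(D, cells, best_idx)
  if (restarts > 1L) {
    for (r in 2:restarts) {
      start <- with_seed(derive_seed(seed, r, 31L), sample.int(g * g, p))
      cand <- climb(start, derive_seed(seed, r))
      cs <- assignment_stress(D, cells, cand)
      if (cs < best_stress) { best_stress <- cs; best_idx <- cand }
    }
  }
  stress <- best_stress
  assign_idx <- best_idx
  structure(list(assignment = cells[assign_idx, , drop = FALSE],
                 grid_side = g, stress = stress,
                 initial_stress = initial_stress,
                 feature_names = d$feature_names),
            class = "refined_map")
}

#' Fit a feature-to-image map from data
#'
#' Convenience wrapper: distance matrix, metric-MDS initialization, and
#' constrained pixel assignment in one call.
#'
#' @param X numeric sample-by-feature matrix.
#' @param grid_side grid side; default \code{ceiling(sqrt(p))}, the smallest
#'   square holding all features.
#' @param metric distance metric, see \code{\link{feature_distance_matrix}}.
#' @param max_iters refinement sweeps.
#' @param seed integer seed.
#' @param restarts hill-climb restarts, see \code{\link{assign_pixels}}.
#' @return a \code{"refined_map"}.
#' @export
refined_map <- function(X, grid_side = NULL, metric = "euclidean",
                        max_iters = 50L, seed = 1L, restarts = NULL) {
  X <- check_numeric_matrix(X)
  g <- as.integer(grid_side %||% ceiling(sqrt(ncol(X))))
  d <- feature_distance_matrix(X, metric)
  co <- initial_embedding(d, g)
  assign_pixels(co, d, g, max_iters = max_iters, seed = seed,
                restarts = restarts)
}

#' @export
print.refined_map <- function(x, ...) {
  cat(sprintf("Feature-to-image map: %d features on a %dx%d grid\n",
              nrow(x$assignment), x$grid_side, x$grid_side))
  cat(sprintf("Embedding stress: %.4f (initial %.4f)\n",
              x$stress, x$initial_stress))
  invisible(x)
}

#' Render one feature vector as an image
#'
#' @param x numeric vector of length p (the map's feature count).
#' @param map a \code{"refined_map"}.
#' @return g x g numeric matrix; unassigned cells are 0.
#' @export
to_image <- function(x, map) {
  stopifnot(inherits(map, "refined_map"))
  p <- nrow(map$assignment)
  if (length(x) != p)
    stop_input("vector length %d does not match the map's %d features",
               length(x), p)
  img <- matrix(0, map$grid_side, map$grid_side)
  img[map$assignment] <- x
  img
}

#' Apply a feature-to-image map to a whole data matrix
#'
#' @param object a \code{"refined_map"}.
#' @param newdata n x p matrix of feature vectors.
#' @param flatten if \code{TRUE} (default) return an n x g^2 matrix of
#'   row-major flattened images (the model input format); otherwise a
#'   g x g x n array.
#' @param ... unused.
#' @export
predict.refined_map <- function(object, newdata, flatten = TRUE, ...) {
  X <- check_numeric_matrix(newdata)
  g <- object$grid_side
  p <- nrow(object$assignment)
  if (ncol(X) != p) stop_input("newdata has %d features; map expects %d",
                               ncol(X), p)
  # row-major flat index of each feature's pixel
  flat <- (object$assignment[, 1L] - 1L) * g + object$assignment[, 2L]
  out <- matrix(0, nrow(X), g * g)
  out[, flat] <- X
  if (flatten) return(out)
  arr <- array(0, c(g, g, nrow(X)))
  for (i in seq_len(nrow(X))) arr[, , i] <- matrix(out[i, ], g, g, byrow = TRUE)
  arr
}

#' Serialize / read a feature map as JSON
#'
#' The JSON object maps each feature name to its 0-based \code{[row, col]}
#' cell, alongside \code{grid_side} and \code{stress}.
#'
#' @param map a \code{"refined_map"}.
#' @param path file path.
#' @return \code{write_refined_map} returns \code{path} invisibly;
#'   \code{read_refined_map} returns a \code{"refined_map"}.
#' @export
write_refined_map <- function(map, path) {
  stopifnot(inherits(map, "refined_map"))
  asg <- lapply(seq_len(nrow(map$assignment)), function(i)
    as.integer(map$assignment[i, ] - 1L))
  names(asg) <- map$feature_names
  jsonlite::write_json(list(grid_side = map$grid_side, stress = map$stress,
                            assignment = asg),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_refined_map
#' @export
read_refined_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asg <- do.call(rbind, obj$assignment) + 1L
  colnames(asg) <- c("row", "col")
  structure(list(assignment = asg, grid_side = as.integer(obj$grid_side),
                 stress = as.numeric(obj$stress),
                 initial_stress = NA_real_,
                 feature_names = names(obj$assignment)),
            class = "refined_map")
}
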