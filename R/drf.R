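#' Training control parameters
#'
#' Collects the tunable constants of the model and training loop. Defaults
#' follow the forest in Fig.-2 style wiring (2 trees of depth 3, hence a
#' 6-unit routing head) and desk-scale optimization settings.
#'
#' @param trees number of trees in the forest.
#' @param depth tree depth (>= 2).
#' @param preset extractor preset, see \code{\link{extractor_spec}}.
#' @param lr SGD learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs (or federation pretraining epochs).
#' @param leaf_iters variational-bounding iterations per leaf update call.
#' @param variance_floor lower bound on leaf variances.
#' @param patience early-stopping patience, in epochs/rounds without
#'   validation improvement.
#' @param lr_patience epochs/rounds of validation plateau before the learning
#'   rate is multiplied by \code{lr_factor}.
#' @param lr_factor learning-rate reduction factor.
#' @param seed integer seed controlling initialization and data shuffling.
#' @return list of class \code{"drf_control"}.
#' @export
drf_control <- function(trees = 2L, depth = 3L, preset = "default",
                        lr = 0.1, batch_size = 32L, epochs = 50L,
                        leaf_iters = 3L, variance_floor = 1e-4,
                        patience = 10L, lr_patience = 5L, lr_factor = 0.5,
                        seed = 1L) {
  ctl <- list(trees = as.integer(trees), depth = as.integer(depth),
              preset = preset, lr = lr, batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), leaf_iters = as.integer(leaf_iters),
              variance_floor = variance_floor, patience = as.integer(patience),
              lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
              seed = as.integer(seed))
  if (ctl$trees < 1L) stop_input("trees must be >= 1")
  if (ctl$depth < 2L) stop_input("depth must be >= 2")
  if (ctl$epochs < 0L) stop_input("epochs must be >= 0")
  class(ctl) <- "drf_control"
  ctl
}

# normalize x into a named list of numeric matrices with equal row counts
as_input_blocks <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) x <- list(x = as.matrix(x))
  if (!is.list(x) || is.null(names(x)) || any(names(x) == ""))
    stop_input("x must be a matrix or a named list of matrices")
  x <- lapply(x, check_numeric_matrix)
  n <- unique(vapply(x, nrow, 0L))
  if (length(n) != 1L) stop_input("input blocks have differing row counts")
  x
}

sigmoid_clamped <- function(z) pmin(pmax(1 / (1 + exp(-z)), 1e-7), 1 - 1e-7)

# loss and head-output gradient for the Gaussian-mixture forest head.
# O: n x (T * n_internal) routing logits. Returns mean NLL over trees and
# batch, the gradient w.r.t. O at that scale, and the per-tree routing
# probabilities (reused for leaf updates).
forest_head <- function(y, O, topo, leaves, want_grad = TRUE) {
  n <- length(y)
  K <- topo$n_internal
  n_trees <- nrow(leaves$mu)
  if (ncol(O) != n_trees * K)
    stop_input("head emits %d outputs but forest consumes %d", ncol(O), n_trees * K)
  S_all <- sigmoid_clamped(O)
  dO <- if (want_grad) matrix(0, n, ncol(O)) else NULL
  loss <- 0
  Plist <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    cols <- (t - 1L) * K + seq_len(K)
    S <- S_all[, cols, drop = FALSE]
    P <- routing_probabilities(S, topo)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    Plist[[t]] <- P
    a <- log(P) + log_gauss(y, leaves$mu[t, ], leaves$s2[t, ])
    m <- apply(a, 1L, max)
    ll <- m + log(rowSums(exp(a - m)))
    loss <- loss + mean(-ll)
    if (want_grad) {
      xi <- exp(a - ll)   # posterior responsibilities, rows sum to 1
      dO[, cols] <- ((xi %*% topo$right) * S - (xi %*% topo$left) * (1 - S)) /
        (n * n_trees)
    }
  }
  list(loss = loss / n_trees, dO = dO, P = Plist)
}

mse_head <- function(y, O, want_grad = TRUE) {
  yhat <- O[, 1L]
  n <- length(y)
  list(loss = mean((y - yhat)^2),
       dO = if (want_grad) matrix(2 * (yhat - y) / n, ncol = 1L) else NULL)
}

# one epoch of SGD on the network with leaves held fixed; deterministic
# given shuffle_seed. Returns updated net and the mean minibatch loss.
train_epoch <- function(net, leaves, topo, x, y, head, lr, batch_size,
                        shuffle_seed) {
  n <- length(y)
  ord <- with_seed(shuffle_seed, sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  loss_sum <- 0
  for (s in starts) {
    idx <- ord[s:min(s + batch_size - 1L, n)]
    xb <- lapply(x, function(m) m[idx, , drop = FALSE])
    yb <- y[idx]
    fw <- nn_forward(net, xb)
    hg <- if (head == "forest") forest_head(yb, fw$out, topo, leaves)
          else mse_head(yb, fw$out)
    if (!is.finite(hg$loss))
      stop_input("non-finite training loss (lr too large?): %s", hg$loss)
    grads <- nn_backward(net, fw$cache, hg$dO)
    net <- sgd_step(net, grads, lr)
    loss_sum <- loss_sum + hg$loss * length(yb)
  }
  list(net = net, loss = loss_sum / n)
}

# routing probabilities of the whole dataset under the current network
model_routing <- function(net, leaves, topo, x) {
  fw <- nn_forward(net, x)
  forest_head(rep(0, nrow(fw$out)), fw$out, topo, leaves, want_grad = FALSE)$P
}

#' Fit a deep regression forest (or a direct-regression baseline)
#'
#' Trains a two-arm feature extractor whose linear head drives either a
#' Gaussian-leaf regression forest (\code{head = "forest"}) or a scalar
#' regression output (\code{head = "linear"}, the CNN/ANN baselines).
#' Training alternates, per epoch, one pass of minibatch SGD on the network
#' parameters (leaves fixed) with a variational-bounding update of the leaf
#' means and variances (network fixed). Leaf distributions start at
#' Normal(1, 1). With a validation set, early stopping and learning-rate
#' plateau reduction are applied on validation NRMSE.
#'
#' @param x a numeric matrix or a named list of numeric matrices (one per
#'   input arm, e.g. \code{list(cell = ..., drug = ...)} of flattened
#'   images), rows = samples.
#' @param y numeric response vector.
#' @param control a \code{\link{drf_control}} list.
#' @param validation optional list \code{list(x = ..., y = ...)} used for
#'   early stopping and reported per-epoch NRMSE.
#' @param head \code{"forest"} for the DRF, \code{"linear"} for direct
#'   regression.
#' @param restore_best if \code{TRUE} (default) and validation is supplied,
#'   the parameters with the best validation NRMSE are restored at the end.
#' @return object of class \code{"drf"} with methods \code{print},
#'   \code{summary}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{coef} and \code{simulate}.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(600), 200, 3)
#' y <- tanh(x[, 1]) + 0.5 * x[, 2] + rnorm(200, sd = 0.1)
#' fit <- drf_fit(x, y, drf_control(preset = "tiny", epochs = 10, seed = 2))
#' round(nrmse(y, fitted(fit)), 2)
#' @export
drf_fit <- function(x, y, control = drf_control(), validation = NULL,
                    head = c("forest", "linear"), restore_best = TRUE) {
  head <- match.arg(head)
  x <- as_input_blocks(x)
  y <- as.numeric(y)
  if (nrow(x[[1L]]) != length(y)) stop_input("x and y row counts disagree")
  topo <- tree_topology(control$depth)
  head_size <- if (head == "forest") control$trees * topo$n_internal else 1L
  widths <- vapply(x, ncol, 0L)
  arch <- extractor_spec(control$preset, widths, head_size)
  net <- nn_init(arch, control$seed)
  leaves <- if (head == "forest") init_leaves(topo, control$trees) else NULL
  model <- structure(list(net = net, leaves = leaves, topo = topo,
                          head = head, control = control,
                          blocks = names(x), widths = widths),
                     class = "drf")
  fit_loop(model, x, y, validation, restore_best)
}

# shared training loop (also used by the server pretraining step)
fit_loop <- function(model, x, y, validation, restore_best = TRUE) {
  ctl <- model$control
  lr <- ctl$lr
  best <- Inf; best_state <- NULL; noimp <- 0L; noimp_lr <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_nrmse = numeric(0), lr = numeric(0))
  for (epoch in seq_len(ctl$epochs)) {
    te <- train_epoch(model$net, model$leaves, model$topo, x, y, model$head,
                      lr, ctl$batch_size, shuffle_seed = ctl$seed + epoch)
    model$net <- te$net
    if (model$head == "forest") {
      Pall <- model_routing(model$net, model$leaves, model$topo, x)
      model$leaves <- update_leaves(y, Pall, model$leaves, ctl$leaf_iters,
                                    ctl$variance_floor)
    }
    vn <- NA_real_
    if (!is.null(validation)) {
      vn <- nrmse(validation$y, predict_internal(model, validation$x))
      if (vn < best - 1e-10) {
        best <- vn; noimp <- 0L; noimp_lr <- 0L
        if (restore_best)
          best_state <- list(net = model$net, leaves = model$leaves)
      } else {
        noimp <- noimp + 1L; noimp_lr <- noimp_lr + 1L
        if (noimp_lr >= ctl$lr_patience) { lr <- lr * ctl$lr_factor; noimp_lr <- 0L }
      }
    }
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = te$loss,
                                   val_nrmse = vn, lr = lr))
    if (!is.null(validation) && noimp >= ctl$patience) break
  }
  if (!is.null(best_state)) {
    model$net <- best_state$net
    model$leaves <- best_state$leaves
  }
  model$history <- hist
  model$fitted.values <- predict_internal(model, x)
  model$y <- y
  model
}

predict_internal <- function(model, x) {
  x <- as_input_blocks(x)
  if (!identical(names(x), model$blocks) ||
      !identical(unname(vapply(x, ncol, 0L)), unname(model$widths)))
    stop_input("newdata blocks do not match the fitted model (%s)",
               paste(model$blocks, model$widths, sep = ":", collapse = ", "))
  O <- nn_forward(model$net, x)$out
  if (model$head == "linear") return(O[, 1L])
  K <- model$topo$n_internal
  S_all <- sigmoid_clamped(O)
  preds <- matrix(0, nrow(O), nrow(model$leaves$mu))
  for (t in seq_len(nrow(model$leaves$mu))) {
    S <- S_all[, (t - 1L) * K + seq_len(K), drop = FALSE]
    P <- routing_probabilities(S, topo = model$topo)
    if (is.null(dim(P))) P <- matrix(P, nrow = 1L)
    preds[, t] <- tree_predict(P, model$leaves$mu[t, ])
  }
  forest_predict(preds)
}

#' @export
predict.drf <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted.values)
  predict_internal(object, newdata)
}

#' @export
fitted.drf <- function(object, ...) object$fitted.values

#' @export
residuals.drf <- function(object, ...) object$y - object$fitted.values

#' @export
coef.drf <- function(object, ...) {
  if (object$head != "forest") return(nn_get_params(object$net))
  list(leaf_mean = object$leaves$mu, leaf_variance = object$leaves$s2)
}

#' @export
print.drf <- function(x, ...) {
  if (x$head == "forest")
    cat(sprintf("Deep regression forest: %d trees, depth %d (%d routing outputs)\n",
                nrow(x$leaves$mu), x$topo$depth,
                nrow(x$leaves$mu) * x$topo$n_internal))
  else cat("Network regressor (direct scalar head)\n")
  cat(sprintf("Extractor preset '%s'; input blocks: %s\n", x$control$preset,
              paste(x$blocks, x$widths, sep = ":", collapse = ", ")))
  if (nrow(x$history) > 0L)
    cat(sprintf("Trained %d epochs; final training loss %.4f\n",
                nrow(x$history), utils::tail(x$history$train_loss, 1)))
  invisible(x)
}

#' @export
summary.drf <- function(object, ...) {
  out <- list(head = object$head,
              epochs = nrow(object$history),
              train_nrmse = nrmse(object$y, object$fitted.values),
              val_nrmse = utils::tail(stats::na.omit(object$history$val_nrmse), 1),
              history = object$history)
  class(out) <- "summary.drf"
  out
}

#' @export
print.summary.drf <- function(x, ...) {
  cat(sprintf("Head: %s | epochs run: %d | training NRMSE: %.4f\n",
              x$head, x$epochs, x$train_nrmse))
  if (length(x$val_nrmse)) cat(sprintf("Best validation NRMSE: %.4f\n", x$val_nrmse))
  invisible(x)
}

#' @export
plot.drf <- function(x, ...) {
  graphics::plot(x$y, x$fitted.values, xlab = "observed", ylab = "fitted",
                 main = "Deep regression forest fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate responses from the fitted forest's predictive mixture
#'
#' Draws each simulated response by picking a tree uniformly, a leaf
#' according to the sample's routing probabilities, then sampling the leaf's
#' Gaussian. For \code{head = "linear"} models, draws are the point
#' prediction plus residual-scale Gaussian noise.
#'
#' @param object fitted \code{"drf"}.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param newdata optional inputs (defaults to the training inputs are not
#'   stored; newdata is required).
#' @param ... unused.
#' @return matrix with one column per simulation.
#' @export
simulate.drf <- function(object, nsim = 1L, seed = 1L, newdata, ...) {
  if (missing(newdata)) stop_input("simulate.drf requires newdata")
  x <- as_input_blocks(newdata)
  n <- nrow(x[[1L]])
  if (object$head == "linear") {
    mu <- predict_internal(object, x)
    sdres <- stats::sd(residuals(object))
    return(with_seed(seed, matrix(stats::rnorm(n * nsim, mu, sdres), n, nsim)))
  }
  O <- nn_forward(object$net, x)$out
  K <- object$topo$n_internal
  S_all <- sigmoid_clamped(O)
  n_trees <- nrow(object$leaves$mu)
  Plist <- lapply(seq_len(n_trees), function(t) {
    P <- routing_probabilities(S_all[, (t - 1L) * K + seq_len(K), drop = FALSE],
                               object$topo)
    if (is.null(dim(P))) matrix(P, nrow = 1L) else P
  })
  with_seed(seed, {
    out <- matrix(0, n, nsim)
    for (j in seq_len(nsim)) {
      tr <- sample.int(n_trees, n, replace = TRUE)
      for (i in seq_len(n)) {
        l <- sample.int(object$topo$n_leaves, 1L, prob = Plist[[tr[i]]][i, ])
        out[i, j] <- stats::rnorm(1L, object$leaves$mu[tr[i], l],
                                  sqrt(object$leaves$s2[tr[i], l]))
      }
    }
    out
  })
}
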