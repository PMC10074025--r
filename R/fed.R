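# Cross-silo horizontal federated learning simulation. Clients never expose
# raw data: the only objects crossing the client boundary are parameter
# sets, sample counts and non-improving-round counters.

# full parameter set of a model as a flat named list (network tensors plus,
# for forest heads, the leaf mean/variance matrices)
model_params <- function(model) {
  ps <- nn_get_params(model$net)
  if (!is.null(model$leaves)) {
    ps[["leaf.mu"]] <- model$leaves$mu
    ps[["leaf.s2"]] <- model$leaves$s2
  }
  ps
}

set_model_params <- function(model, params) {
  model$net <- nn_set_params(model$net, params)
  if (!is.null(model$leaves)) {
    model$leaves$mu <- params[["leaf.mu"]]
    model$leaves$s2 <- params[["leaf.s2"]]
    class(model$leaves) <- "drf_leaves"
  }
  model
}

#' Data-weighted federated averaging of parameter sets
#'
#' Element-wise weighted mean of every tensor across client updates —
#' network weights and, for forest models, leaf means and variances alike.
#' Aggregated leaf variances are re-floored at \code{variance_floor}.
#'
#' @param updates list of parameter sets (flat named lists of numeric
#'   arrays, as exchanged by clients); all must share names and shapes.
#' @param weights numeric vector of non-negative client weights (default:
#'   equal); normalized internally to sum to 1.
#' @param variance_floor floor applied to \code{"leaf.s2"} if present.
#' @return aggregated parameter set.
#' @export
federated_average <- function(updates, weights = NULL, variance_floor = 1e-4) {
  if (!length(updates)) stop_input("no client updates to aggregate")
  nms <- names(updates[[1L]])
  weights <- weights %||% rep(1, length(updates))
  if (length(weights) != length(updates))
    stop_input("need one weight per update")
  if (any(weights < 0) || sum(weights) <= 0)
    stop_input("weights must be non-negative with positive sum")
  w <- weights / sum(weights)
  for (u in updates) {
    if (!identical(names(u), nms))
      stop_input("client update parameter names disagree")
  }
  agg <- updates[[1L]]
  for (key in nms) {
    ref_dim <- dim(updates[[1L]][[key]])
    acc <- updates[[1L]][[key]] * w[1L]
    for (i in seq_along(updates)[-1L]) {
      v <- updates[[i]][[key]]
      if (!identical(dim(v), ref_dim) ||
          length(v) != length(updates[[1L]][[key]]))
        stop_input("shape mismatch while aggregating tensor '%s'", key)
      acc <- acc + v * w[i]
    }
    agg[[key]] <- acc
  }
  if (!is.null(agg[["leaf.s2"]]))
    agg[["leaf.s2"]] <- pmax(agg[["leaf.s2"]], variance_floor)
  agg
}

#' One client round: local epoch plus leaf update
#'
#' The client initializes from the broadcast global parameters, runs exactly
#' one epoch of minibatch SGD on its local data, then (for forest heads) one
#' leaf-parameter update pass. The return value contains only parameters,
#' the local sample count, the client's non-improving-round counter and its
#' local training loss — never data.
#'
#' @param global_params broadcast parameter set.
#' @param model model skeleton (architecture carrier; parameters are
#'   overwritten by \code{global_params}).
#' @param x,y the client's local data (named list of blocks, response).
#' @param control a \code{\link{drf_control}}.
#' @param round_seed seed for this round's data shuffle.
#' @param lr current learning rate.
#' @param prev_best,prev_noimp client-side running best loss / counter.
#' @return list(params, n, non_improving, train_loss, best_loss).
#' @export
client_update <- function(global_params, model, x, y, control, round_seed,
                          lr = control$lr, prev_best = Inf, prev_noimp = 0L) {
  n <- length(y)
  if (n == 0L) {
    warning("client has no data; skipped with weight 0")
    return(list(params = global_params, n = 0L, non_improving = prev_noimp,
                train_loss = NA_real_, best_loss = prev_best))
  }
  model <- set_model_params(model, global_params)
  te <- train_epoch(model$net, model$leaves, model$topo, x, y, model$head,
                    lr, control$batch_size, shuffle_seed = round_seed)
  model$net <- te$net
  if (model$head == "forest" && control$leaf_iters > 0L) {
    Pall <- model_routing(model$net, model$leaves, model$topo, x)
    model$leaves <- update_leaves(y, Pall, model$leaves, control$leaf_iters,
                                  control$variance_floor)
  }
  improved <- te$loss < prev_best - 1e-10
  list(params = model_params(model), n = n,
       non_improving = if (improved) 0L else prev_noimp + 1L,
       train_loss = te$loss,
       best_loss = min(prev_best, te$loss))
}

#' Pretrain the initial global model on the server's proxy data
#'
#' Trains a fresh model to convergence on the server's initial training set
#' with early stopping on the validation set; this becomes the round-0
#' broadcast. With no initial data, a randomly initialized model is
#' returned with a warning.
#'
#' @param x,y server initial training data (may have zero rows).
#' @param widths named integer vector of input block widths (used when
#'   \code{x} is empty).
#' @param control a \code{\link{drf_control}}; \code{control$epochs} bounds
#'   the pretraining epochs (0 returns the random initialization unchanged).
#' @param validation optional list(x, y) for early stopping.
#' @param head \code{"forest"} or \code{"linear"}.
#' @return a fitted \code{"drf"} model (the initial global model).
#' @export
pretrain_server <- function(x, y, control = drf_control(), validation = NULL,
                            head = "forest", widths = NULL) {
  x <- as_input_blocks(x)
  if (length(y) == 0L || nrow(x[[1L]]) == 0L) {
    warning("empty server initial set: falling back to random initialization")
    ctl0 <- control; ctl0$epochs <- 0L
    wid <- widths %||% vapply(x, ncol, 0L)
    dummy <- lapply(wid, function(w) matrix(0, 1L, w))
    return(drf_fit(dummy, 0, ctl0, head = head))
  }
  drf_fit(x, y, control, validation = validation, head = head)
}

#' Run a cross-silo federated simulation
#'
#' Implements the round loop: broadcast the global parameters, let every
#' client run \code{\link{client_update}}, compute each client's validation
#' NRMSE on the server's validation set \emph{before} aggregation, then form
#' the new global model by \code{\link{federated_average}} with
#' sample-count (or uniform) weights. The aggregated model's validation
#' NRMSE drives learning-rate plateau reduction and early stopping. In
#' \code{mode = "personalized"} the final trunk layer is excluded from
#' aggregation — every client keeps its own copy — and the stopping/LR
#' counters are the mean of the clients' non-improving counters.
#'
#' @param data list with blocks \code{x} (named list of input matrices over
#'   all samples) and \code{y}.
#' @param partition a \code{\link{split_random}} /
#'   \code{\link{split_quasi_random}} partition (sample indices).
#' @param control a \code{\link{drf_control}}; \code{control$epochs} is the
#'   server pretraining budget.
#' @param rounds number of federation rounds M (>= 1).
#' @param mode \code{"standard"} or \code{"personalized"}.
#' @param head \code{"forest"} (DRF) or \code{"linear"} (CNN/ANN).
#' @param weighting \code{"samples"} (data-weighted, default) or
#'   \code{"uniform"}.
#' @param pretrain if \code{FALSE}, skip server pretraining (random round-0
#'   broadcast).
#' @return object of class \code{"federation"}: the final global
#'   \code{model}, per-round per-client \code{history} (round, client,
#'   val_nrmse, n_samples, lr), the aggregated-model validation trace,
#'   client personalized layers (personalized mode), and the configuration.
#' @export
run_federation <- function(data, partition, control = drf_control(),
                           rounds = 20L, mode = c("standard", "personalized"),
                           head = "forest", weighting = c("samples", "uniform"),
                           pretrain = TRUE) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  rounds <- as.integer(rounds)
  if (rounds < 1L) stop_input("rounds must be >= 1")
  x <- as_input_blocks(data$x)
  y <- as.numeric(data$y)
  take <- function(idx) list(x = lapply(x, function(m) m[idx, , drop = FALSE]),
                             y = y[idx])
  dv <- take(partition$val)
  init <- take(partition$train_init)
  # server pretraining (round-0 broadcast)
  ctl0 <- control
  if (!pretrain) ctl0$epochs <- 0L
  global <- pretrain_server(init$x, init$y, ctl0, validation = dv, head = head)
  skeleton <- global
  gparams <- model_params(global)
  n_clients <- length(partition$clients)
  client_data <- lapply(partition$clients, take)
  persl <- if (mode == "personalized") last_layer_names(global$net) else character(0)
  personal <- replicate(n_clients, gparams[persl], simplify = FALSE)
  lr <- control$lr
  best <- Inf; noimp <- 0L; noimp_lr <- 0L; last_halve <- 0L
  cl_best <- rep(Inf, n_clients); cl_noimp <- rep(0L, n_clients)
  history <- NULL
  agg_trace <- numeric(0)
  for (t in seq_len(rounds)) {
    updates <- vector("list", n_clients)
    ns <- integer(n_clients)
    for (j in seq_len(n_clients)) {
      bcast <- gparams
      if (length(persl)) bcast[persl] <- personal[[j]]
      up <- client_update(bcast, skeleton, client_data[[j]]$x,
                          client_data[[j]]$y, control,
                          round_seed = control$seed + t, lr = lr,
                          prev_best = cl_best[j], prev_noimp = cl_noimp[j])
      cl_best[j] <- up$best_loss
      cl_noimp[j] <- up$non_improving
      updates[[j]] <- up$params
      ns[j] <- up$n
    }
    # per-client validation loss on DV before aggregation
    val_j <- vapply(seq_len(n_clients), function(j) {
      m <- set_model_params(skeleton, updates[[j]])
      nrmse(dv$y, predict_internal(m, dv$x))
    }, 0)
    history <- rbind(history,
                     data.frame(round = t, client = seq_len(n_clients),
                                val_nrmse = val_j, n_samples = ns, lr = lr))
    if (length(persl)) {
      for (j in seq_len(n_clients)) personal[[j]] <- updates[[j]][persl]
      updates <- lapply(updates, function(u) u[setdiff(names(u), persl)])
    }
    live <- ns > 0L
    w <- switch(weighting, samples = ns[live], uniform = rep(1, sum(live)))
    agg <- federated_average(updates[live], w, control$variance_floor)
    if (length(persl)) {
      gparams[names(agg)] <- agg
      # monitoring only: the server's view of the personalized layer is the
      # plain mean of the client copies; clients never receive it
      gparams[persl] <- federated_average(personal[live], w)
    } else gparams <- agg
    # server-side schedule on the aggregated model's validation NRMSE;
    # in personalized mode the averaged client counters drive it instead
    gm <- set_model_params(skeleton, gparams)
    agg_val <- nrmse(dv$y, predict_internal(gm, dv$x))
    agg_trace <- c(agg_trace, agg_val)
    if (mode == "standard") {
      if (agg_val < best - 1e-10) {
        best <- agg_val; noimp <- 0L; noimp_lr <- 0L
      } else {
        noimp <- noimp + 1L; noimp_lr <- noimp_lr + 1L
        if (noimp_lr >= control$lr_patience) { lr <- lr * control$lr_factor; noimp_lr <- 0L }
      }
      if (noimp >= control$patience) break
    } else {
      mean_noimp <- mean(cl_noimp)
      if (mean_noimp >= control$lr_patience && t - last_halve >= control$lr_patience) {
        lr <- lr * control$lr_factor
        last_halve <- t
      }
      if (mean_noimp >= control$patience) break
    }
  }
  final <- set_model_params(skeleton, gparams)
  final$fitted.values <- NULL; final$y <- NULL; final$history <- NULL
  structure(list(model = final, history = history, agg_val_nrmse = agg_trace,
                 personal = if (length(persl)) personal,
                 personal_layer = persl,
                 mode = mode, head = head, weighting = weighting,
                 rounds_run = max(history$round), control = control,
                 n_clients = n_clients),
            class = "federation")
}

#' @export
print.federation <- function(x, ...) {
  cat(sprintf("Federated %s (%s mode): %d clients, %d rounds run\n",
              if (x$head == "forest") "deep regression forest" else "network regressor",
              x$mode, x$n_clients, x$rounds_run))
  cat(sprintf("Final aggregated validation NRMSE: %.4f\n",
              utils::tail(x$agg_val_nrmse, 1)))
  invisible(x)
}

#' @export
summary.federation <- function(object, ...) {
  h <- object$history
  last <- h[h$round == max(h$round), ]
  out <- list(mode = object$mode, n_clients = object$n_clients,
              rounds = object$rounds_run,
              final_val = utils::tail(object$agg_val_nrmse, 1),
              client_val_spread = stats::sd(last$val_nrmse))
  class(out) <- "summary.federation"
  out
}

#' @export
print.summary.federation <- function(x, ...) {
  cat(sprintf("%s federation: %d clients, %d rounds\n", x$mode, x$n_clients, x$rounds))
  cat(sprintf("final aggregated val NRMSE %.4f; client val spread (sd) %.4f\n",
              x$final_val, x$client_val_spread))
  invisible(x)
}

#' Plot per-client validation-loss trajectories
#'
#' @param x a \code{"federation"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.federation <- function(x, ...) {
  h <- x$history
  M <- stats::reshape(h[c("round", "client", "val_nrmse")],
                      direction = "wide", idvar = "round", timevar = "client")
  graphics::matplot(M$round, as.matrix(M[-1L]), type = "l", lty = 1,
                    xlab = "round", ylab = "validation NRMSE",
                    main = "Per-client validation trajectories", ...)
  invisible(x)
}

#' @export
predict.federation <- function(object, newdata, ...) {
  predict_internal(object$model, newdata)
}

#' Write the federation round log as CSV
#'
#' Columns: round, client_id, val_nrmse, n_samples, lr.
#'
#' @param fed a \code{"federation"}.
#' @param path output file.
#' @export
write_round_log <- function(fed, path) {
  stopifnot(inherits(fed, "federation"))
  h <- fed$history
  names(h)[names(h) == "client"] <- "client_id"
  utils::write.csv(h, path, row.names = FALSE)
  invisible(path)
}
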