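# Experiment orchestration: centralized vs initial vs federated vs
# per-client baselines on synthetic studies, with replicate averaging.

take_rows <- function(x, y, idx)
  list(x = lapply(x, function(m) m[idx, , drop = FALSE]), y = y[idx])

# fit the feature-to-image maps on the server's initial training samples
fit_maps <- function(study, partition, seed = 1L) {
  s <- study$samples[partition$train_init, , drop = FALSE]
  list(cell = refined_map(study$cell_features[s$cell, , drop = FALSE],
                          seed = derive_seed(seed, 11L)),
       drug = refined_map(study$drug_features[s$drug, , drop = FALSE],
                          seed = derive_seed(seed, 13L)))
}

model_setup <- function(model, study, partition, seed) {
  if (model == "ann") {
    inp <- prepare_inputs(study, NULL)
    list(inputs = inp, head = "linear", preset = "ann", maps = NULL)
  } else {
    maps <- fit_maps(study, partition, seed)
    inp <- prepare_inputs(study, maps)
    list(inputs = inp,
         head = if (model == "refined_drf") "forest" else "linear",
         preset = "default", maps = maps)
  }
}

#' Train and evaluate individually trained client models
#'
#' Every client trains alone on its local share with a reduced-complexity
#' preset and batch size 12, holding out a 10\% local validation subset for
#' early stopping; no parameters are exchanged. Evaluation modes:
#' \describe{
#'   \item{global}{each client model is evaluated on the partition's
#'     hold-out set (one metric row per client).}
#'   \item{local_global}{each client additionally holds out 10\% of its own
#'     samples; models are scored on their own local hold-out and on the
#'     concatenation of all clients' local hold-outs (two rows per client).}
#' }
#'
#' @param data model-ready inputs from \code{\link{prepare_inputs}}.
#' @param partition a \code{"fed_partition"}.
#' @param control a \code{\link{drf_control}} (batch size forced to 12 and
#'   preset to \code{"reduced"} unless already \code{"ann"}).
#' @param head \code{"forest"} or \code{"linear"}.
#' @param evaluation \code{"global"} or \code{"local_global"}.
#' @return list with \code{models} (per-client fits) and \code{metrics}
#'   data.frame (client, setting, nrmse, pcc).
#' @export
run_client_baselines <- function(data, partition, control = drf_control(),
                                 head = "forest",
                                 evaluation = c("global", "local_global")) {
  evaluation <- match.arg(evaluation)
  x <- as_input_blocks(data$x)
  y <- as.numeric(data$y)
  ctl <- control
  ctl$batch_size <- 12L
  if (ctl$preset != "ann") ctl$preset <- "reduced"
  n_clients <- length(partition$clients)
  models <- vector("list", n_clients)
  rows <- NULL
  local_hold <- vector("list", n_clients)
  val_idx <- vector("list", n_clients)
  train_idx <- vector("list", n_clients)
  for (j in seq_len(n_clients)) {
    idx <- partition$clients[[j]]
    idx <- with_seed(derive_seed(control$seed, j, 3L), sample(idx))
    n_j <- length(idx)
    if (n_j < 4L) {
      warning(sprintf("client %d too small (%d samples) for a validation split", j, n_j))
      local_hold[[j]] <- integer(0); val_idx[[j]] <- integer(0)
      train_idx[[j]] <- idx
      next
    }
    n_holdout <- if (evaluation == "local_global") max(1L, round(0.1 * n_j)) else 0L
    n_val <- max(1L, round(0.1 * n_j))
    local_hold[[j]] <- if (n_holdout) idx[seq_len(n_holdout)] else integer(0)
    val_idx[[j]] <- idx[n_holdout + seq_len(n_val)]
    train_idx[[j]] <- idx[(n_holdout + n_val + 1L):n_j]
  }
  for (j in seq_len(n_clients)) {
    ctl_j <- ctl
    ctl_j$seed <- derive_seed(control$seed, j)
    tr <- take_rows(x, y, train_idx[[j]])
    va <- take_rows(x, y, val_idx[[j]])
    fit <- tryCatch(
      drf_fit(tr$x, tr$y, ctl_j, validation = if (length(va$y) >= 2) va,
              head = head),
      error = function(e) stop_input("client %d baseline failed: %s", j,
                                     conditionMessage(e)))
    models[[j]] <- fit
    if (evaluation == "global") {
      te <- take_rows(x, y, partition$holdout)
      yhat <- predict(fit, te$x)
      rows <- rbind(rows, data.frame(client = j, setting = "global",
                                     nrmse = nrmse(te$y, yhat),
                                     pcc = pcc(te$y, yhat)))
    }
  }
  if (evaluation == "local_global") {
    glob_idx <- unlist(local_hold)
    for (j in seq_len(n_clients)) {
      loc <- take_rows(x, y, local_hold[[j]])
      glo <- take_rows(x, y, glob_idx)
      if (length(loc$y) >= 2) {
        yl <- predict(models[[j]], loc$x)
        rows <- rbind(rows, data.frame(client = j, setting = "local",
                                       nrmse = nrmse(loc$y, yl),
                                       pcc = pcc(loc$y, yl)))
      }
      yg <- predict(models[[j]], glo$x)
      rows <- rbind(rows, data.frame(client = j, setting = "global",
                                     nrmse = nrmse(glo$y, yg),
                                     pcc = pcc(glo$y, yg)))
    }
  }
  list(models = models, metrics = rows)
}

#' Run a replicated federated-vs-baseline experiment
#'
#' For every replicate seed: generate a synthetic study, partition it, fit
#' the feature-to-image maps on the server's initial set (REFINED models),
#' pretrain the server, run the federation, and score the final global
#' model on the hold-out set; optionally also score the initial (round-0)
#' server model, the centralized model (all training data pooled) and the
#' individually trained client baselines. Metric rows are averaged over
#' replicates.
#'
#' @param models character vector from \code{c("refined_drf",
#'   "refined_cnn", "ann")}.
#' @param n_clients federation size (e.g. 3, 5, 10, 15, 20).
#' @param rounds federation rounds.
#' @param replicates integer vector of replicate seeds (default 1:3, the
#'   three-random-split reporting convention).
#' @param study_args list of arguments to \code{\link{generate_study}}
#'   (the replicate seed is appended).
#' @param partition_mode \code{"random"} or \code{"quasi_random"}.
#' @param k drugs per client for quasi-random partitions.
#' @param control a \code{\link{drf_control}}.
#' @param mode federation mode: \code{"standard"} or \code{"personalized"}.
#' @param include character subset of \code{c("federated", "initial",
#'   "centralized", "clients")} selecting which settings to evaluate.
#' @param permute_fraction if positive, each client's training targets are
#'   permuted by this fraction before federated training (data-swap
#'   robustness protocol).
#' @return object of class \code{"comparison_report"}: \code{metrics}
#'   (per-replicate rows), \code{means}, and the echoed configuration.
#' @export
run_experiment <- function(models = "refined_drf", n_clients = 5L,
                           rounds = 20L, replicates = 1:3,
                           study_args = list(), partition_mode = "random",
                           k = NULL, control = drf_control(),
                           mode = "standard",
                           include = c("federated", "initial"),
                           permute_fraction = 0) {
  models <- match.arg(models, c("refined_drf", "refined_cnn", "ann"),
                      several.ok = TRUE)
  rows <- NULL
  for (r in replicates) {
    study <- do.call(generate_study, c(study_args, list(seed = r)))
    part <- if (partition_mode == "random")
      split_random(study, n_clients, seed = derive_seed(r, 5L))
    else split_quasi_random(study, n_clients, k = k, seed = derive_seed(r, 5L))
    for (model in models) {
      ms <- model_setup(model, study, part, seed = r)
      inp <- ms$inputs
      ctl <- control
      ctl$seed <- derive_seed(control$seed, r)
      if (model == "ann") ctl$preset <- "ann"
      x <- as_input_blocks(inp$x)
      y <- inp$y
      if (permute_fraction > 0) {
        for (j in seq_along(part$clients)) {
          idx <- part$clients[[j]]
          y[idx] <- permute_targets(y[idx], permute_fraction,
                                    seed = derive_seed(r, j, 17L))
        }
      }
      te <- take_rows(x, study$samples$y, part$holdout)
      score <- function(setting, yhat)
        data.frame(model = model, setting = setting, replicate = r,
                   nrmse = nrmse(te$y, yhat), pcc = pcc(te$y, yhat))
      if ("federated" %in% include || "initial" %in% include) {
        fed <- run_federation(list(x = x, y = y), part, ctl, rounds = rounds,
                              mode = mode, head = ms$head)
        if ("federated" %in% include)
          rows <- rbind(rows, score("federated", predict(fed, te$x)))
        if ("initial" %in% include) {
          init <- pretrain_server(take_rows(x, y, part$train_init)$x,
                                  y[part$train_init], ctl,
                                  validation = take_rows(x, y, part$val),
                                  head = ms$head)
          rows <- rbind(rows, score("initial", predict(init, te$x)))
        }
      }
      if ("centralized" %in% include) {
        pooled <- c(part$train_init, unlist(part$clients))
        cent <- drf_fit(take_rows(x, y, pooled)$x, y[pooled], ctl,
                        validation = take_rows(x, y, part$val),
                        head = ms$head)
        rows <- rbind(rows, score("centralized", predict(cent, te$x)))
      }
      if ("clients" %in% include) {
        ctl_b <- ctl
        ctl_b$preset <- if (model == "ann") "ann" else "reduced"
        cb <- run_client_baselines(list(x = x, y = y), part, ctl_b,
                                   head = ms$head, evaluation = "global")
        rows <- rbind(rows,
                      data.frame(model = model, setting = "clients",
                                 replicate = r,
                                 nrmse = mean(cb$metrics$nrmse),
                                 pcc = mean(cb$metrics$pcc)))
      }
    }
  }
  structure(list(metrics = rows, means = average_replicates(rows),
                 config = list(models = models, n_clients = n_clients,
                               rounds = rounds, replicates = replicates,
                               partition_mode = partition_mode, k = k,
                               mode = mode, include = include,
                               permute_fraction = permute_fraction,
                               study_args = study_args, control = control)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison report (means over replicates):\n")
  print(x$means, row.names = FALSE)
  invisible(x)
}

#' Relative improvement between two settings or models
#'
#' Improvement of b over a is \code{(a - b) / a * 100} on NRMSE (lower is
#' better) and \code{(b - a) / a * 100} on PCC (higher is better), computed
#' on replicate means.
#'
#' @param report a \code{\link{run_experiment}} result.
#' @param a,b lists \code{list(model =, setting =)} naming the two rows of
#'   the means table to compare.
#' @return named vector \code{c(nrmse_pct, pcc_pct)}.
#' @export
improvement_pct <- function(report, a, b) {
  m <- report$means
  pick <- function(s) {
    row <- m[m$model == s$model & m$setting == s$setting, ]
    if (nrow(row) != 1L) stop_input("no unique row for %s/%s", s$model, s$setting)
    row
  }
  ra <- pick(a); rb <- pick(b)
  c(nrmse_pct = (ra$nrmse - rb$nrmse) / ra$nrmse * 100,
    pcc_pct = (rb$pcc - ra$pcc) / ra$pcc * 100)
}
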