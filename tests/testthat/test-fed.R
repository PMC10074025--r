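test_that("federated averaging identities: single client, idempotence, weighting", {
  p1 <- list(W = matrix(0.3, 2, 2), b = c(1, -1), leaf.mu = matrix(0, 1, 2),
             leaf.s2 = matrix(1, 1, 2))
  # single client: exact identity
  expect_identical(federated_average(list(p1), 1), p1)
  # identical clients: idempotence
  expect_equal(federated_average(list(p1, p1, p1), c(2, 5, 1)), p1)
  # two scalars 0 and 1 with weights 1:3 -> 0.75
  a <- list(w = 0); b <- list(w = 1)
  expect_equal(federated_average(list(a, b), c(1, 3))$w, 0.75)
  # linearity: aggregate of scaled params is the scaled aggregate
  p2 <- lapply(p1, function(v) v * 2)
  agg1 <- federated_average(list(p1, p2), c(1, 2))
  agg3 <- federated_average(list(lapply(p1, function(v) v * 3),
                                 lapply(p2, function(v) v * 3)), c(1, 2))
  expect_equal(lapply(agg1, function(v) v * 3)[c("W", "b", "leaf.mu")],
               agg3[c("W", "b", "leaf.mu")])
  # leaf variances are re-floored
  lo <- list(leaf.s2 = matrix(1e-9, 1, 1))
  expect_equal(federated_average(list(lo), 1, variance_floor = 1e-4)$leaf.s2[1],
               1e-4)
  # errors name the offending tensor / misuse
  bad <- p1; bad$W <- matrix(0, 3, 3)
  expect_error(federated_average(list(p1, bad), c(1, 1)), "'W'")
  expect_error(federated_average(list(), NULL), "no client updates")
  expect_error(federated_average(list(p1, p1), c(1, -1)), "non-negative")
})

test_that("client update: identity at zero learning rate, counts, determinism, privacy", {
  dat <- tiny_two_arm_data(n = 40, g = 3, seed = 8)
  ctl <- drf_control(preset = "tiny", trees = 2, depth = 3, seed = 4,
                     leaf_iters = 0)
  model <- drf_fit(dat$x, dat$y, modifyList(ctl, list(epochs = 0L)))
  gp <- fedrf:::model_params(model)
  up0 <- client_update(gp, model, dat$x, dat$y, ctl, round_seed = 9, lr = 0)
  expect_equal(up0$params, gp)                        # zero lr + zero leaf iters
  expect_equal(up0$n, 40L)
  # identical clients produce identical updates
  ctl$leaf_iters <- 3L
  u1 <- client_update(gp, model, dat$x, dat$y, ctl, round_seed = 9)
  u2 <- client_update(gp, model, dat$x, dat$y, ctl, round_seed = 9)
  expect_identical(u1$params, u2$params)
  # privacy contract: only parameters, counts and loss scalars cross the wire
  expect_named(u1, c("params", "n", "non_improving", "train_loss", "best_loss"))
  expect_true(all(vapply(u1$params, is.numeric, TRUE)))
  # empty client is skipped with weight 0
  expect_warning(
    ue <- client_update(gp, model,
                        lapply(dat$x, function(m) m[0, , drop = FALSE]),
                        numeric(0), ctl, round_seed = 1),
    "no data")
  expect_equal(ue$n, 0L)
})

test_that("an n = 1 federation reproduces centralized training bit-for-bit", {
  ts <- tiny_partitioned_study(n_cells = 20, n_drugs = 6, seed = 3,
                               n_clients = 1)
  ctl <- drf_control(preset = "tiny", trees = 2, depth = 3, seed = 11,
                     lr = 0.1, batch_size = 16, epochs = 3,
                     patience = 100, lr_patience = 100)
  fed <- run_federation(list(x = ts$inp$x, y = ts$inp$y), ts$part, ctl,
                        rounds = 3, mode = "standard", head = "forest",
                        pretrain = FALSE)
  # plain training loop on the same client data, same seed schedule
  idx <- ts$part$clients[[1]]
  xc <- lapply(fedrf:::as_input_blocks(ts$inp$x),
               function(m) m[idx, , drop = FALSE])
  cent <- drf_fit(xc, ts$inp$y[idx], modifyList(ctl, list(epochs = 3L)))
  expect_identical(fedrf:::model_params(fed$model), fedrf:::model_params(cent))
})

test_that("standard federation runs, logs per-client losses, and broadcasts uniformly", {
  ts <- tiny_partitioned_study(n_cells = 30, n_drugs = 8, seed = 5,
                               n_clients = 3)
  ctl <- drf_control(preset = "tiny", seed = 2, epochs = 2, batch_size = 16)
  fed <- run_federation(list(x = ts$inp$x, y = ts$inp$y), ts$part, ctl,
                        rounds = 4, head = "forest")
  h <- fed$history
  # one log entry per client per completed round
  expect_equal(nrow(h), 3 * fed$rounds_run)
  expect_true(all(table(h$round) == 3))
  expect_true(all(is.finite(h$val_nrmse)))
  expect_equal(sort(unique(h$n_samples)),
               sort(unique(lengths(ts$part$clients))))
  # round-log CSV round trip
  f <- tempfile(fileext = ".csv")
  write_round_log(fed, f)
  back <- read.csv(f)
  expect_equal(back$val_nrmse, h$val_nrmse)
  unlink(f)
  # determinism of the whole loop
  fed2 <- run_federation(list(x = ts$inp$x, y = ts$inp$y), ts$part, ctl,
                         rounds = 4, head = "forest")
  expect_identical(fedrf:::model_params(fed$model),
                   fedrf:::model_params(fed2$model))
})

test_that("personalized mode keeps client-specific last layers, shares the rest", {
  ts <- tiny_partitioned_study(n_cells = 30, n_drugs = 8, seed = 6,
                               n_clients = 3)
  ctl <- drf_control(preset = "tiny", seed = 7, epochs = 2, batch_size = 16)
  fed <- run_federation(list(x = ts$inp$x, y = ts$inp$y), ts$part, ctl,
                        rounds = 3, mode = "personalized", head = "forest")
  expect_length(fed$personal, 3)
  persl <- fed$personal_layer
  expect_true(all(grepl("^trunk", persl)))
  # client last layers differ...
  W1 <- fed$personal[[1]][[persl[1]]]
  W2 <- fed$personal[[2]][[persl[1]]]
  expect_false(isTRUE(all.equal(W1, W2)))
  # ...while the shared layers live in a single aggregated copy that every
  # client receives; the model still predicts and logs all clients
  expect_true(all(persl %in% names(fedrf:::model_params(fed$model))))
  expect_equal(nrow(fed$history), 3 * fed$rounds_run)
})

test_that("pretraining falls back to random init on empty server data", {
  dat <- tiny_two_arm_data(n = 10, g = 3, seed = 1)
  ctl <- drf_control(preset = "tiny", epochs = 5, seed = 3)
  empty <- lapply(dat$x, function(m) m[0, , drop = FALSE])
  expect_warning(m0 <- pretrain_server(empty, numeric(0), ctl), "empty server")
  expect_s3_class(m0, "drf")
  # zero allowed epochs returns the initialization unchanged
  ctl0 <- modifyList(ctl, list(epochs = 0L))
  a <- drf_fit(dat$x, dat$y, ctl0)
  b <- drf_fit(dat$x, dat$y, ctl0)
  expect_identical(fedrf:::model_params(a), fedrf:::model_params(b))
})
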