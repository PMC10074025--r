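# Synthetic drug-response-like study generator and client partition
# protocols. The generator emulates the shape of a cell-line x drug
# screening panel (default 504 cell lines x 24 drugs): block-correlated
# cell and drug descriptor matrices, and a response that mixes a bilinear
# cell-drug interaction, smooth per-arm nonlinearities, a per-drug cluster
# offset and Gaussian noise.

#' Generate a synthetic drug-response study
#'
#' Features come in correlated blocks (each block = shared latent factor +
#' idiosyncratic noise) so the feature-to-image mapping has real
#' neighbourhood structure to discover. The response for a (cell, drug)
#' pair is
#' \deqn{y = u_c^\top A v_d + \tanh(w_c^\top x_c) + \tanh(w_d^\top x_d)
#'       + \mathrm{cluster\_effect}\cdot\delta_d + \epsilon,}
#' with \eqn{u_c, v_d} the latent block factors, \eqn{\delta_d} a standard
#' normal per-drug offset and \eqn{\epsilon \sim N(0,
#' \mathrm{noise\_sd}^2)}. Fully reproducible from \code{seed}.
#'
#' @param n_cells,n_drugs panel dimensions (defaults mirror a 504 x 24
#'   screening panel).
#' @param p_cell,p_drug number of cell / drug descriptors.
#' @param noise_sd response noise standard deviation (default 0.3; the
#'   signal has unit-order scale).
#' @param cluster_effect scale of the per-drug cluster offset (default 1).
#' @param seed integer seed.
#' @return object of class \code{"synthetic_study"}: \code{cell_features}
#'   (n_cells x p_cell), \code{drug_features} (n_drugs x p_drug),
#'   \code{samples} data.frame (cell, drug, y) over all pairs, and the
#'   generation parameters.
#' @export
generate_study <- function(n_cells = 504L, n_drugs = 24L, p_cell = 48L,
                           p_drug = 32L, noise_sd = 0.3, cluster_effect = 1,
                           seed = 1L) {
  if (min(n_cells, n_drugs, p_cell, p_drug) < 1L)
    stop_input("all sizes must be positive")
  with_seed(seed, {
    block_mat <- function(n, p, n_latent) {
      U <- matrix(stats::rnorm(n * n_latent), n, n_latent)
      blocks <- rep(seq_len(n_latent), length.out = p)
      X <- U[, blocks, drop = FALSE] + 0.5 * matrix(stats::rnorm(n * p), n, p)
      # effective latent factors are the observable block means, so that
      # with noise_sd = 0 the response is an exact function of the features
      Ueff <- vapply(seq_len(n_latent), function(b)
        rowMeans(X[, blocks == b, drop = FALSE]), numeric(n))
      list(X = X, U = Ueff)
    }
    kc <- max(2L, min(6L, p_cell %/% 8L))
    kd <- max(2L, min(4L, p_drug %/% 8L))
    cell <- block_mat(n_cells, p_cell, kc)
    drug <- block_mat(n_drugs, p_drug, kd)
    A <- matrix(stats::rnorm(kc * kd, sd = 1 / sqrt(kc * kd)), kc, kd)
    w_c <- stats::rnorm(p_cell, sd = 1 / sqrt(p_cell))
    w_d <- stats::rnorm(p_drug, sd = 1 / sqrt(p_drug))
    delta <- stats::rnorm(n_drugs)
    pairs <- expand.grid(cell = seq_len(n_cells), drug = seq_len(n_drugs))
    bilin <- rowSums((cell$U[pairs$cell, , drop = FALSE] %*% A) *
                       drug$U[pairs$drug, , drop = FALSE])
    y <- bilin + tanh(cell$X[pairs$cell, , drop = FALSE] %*% w_c) +
      tanh(drug$X[pairs$drug, , drop = FALSE] %*% w_d) +
      cluster_effect * delta[pairs$drug] +
      stats::rnorm(nrow(pairs), sd = noise_sd)
    colnames(cell$X) <- paste0("c", seq_len(p_cell))
    colnames(drug$X) <- paste0("d", seq_len(p_drug))
    structure(list(cell_features = cell$X, drug_features = drug$X,
                   samples = data.frame(cell = pairs$cell, drug = pairs$drug,
                                        y = as.numeric(y)),
                   drug_offsets = cluster_effect * delta,
                   params = list(n_cells = n_cells, n_drugs = n_drugs,
                                 p_cell = p_cell, p_drug = p_drug,
                                 noise_sd = noise_sd,
                                 cluster_effect = cluster_effect,
                                 seed = as.integer(seed))),
              class = "synthetic_study")
  })
}

#' @export
print.synthetic_study <- function(x, ...) {
  p <- x$params
  cat(sprintf("Synthetic drug-response study: %d cells x %d drugs (%d samples)\n",
              p$n_cells, p$n_drugs, nrow(x$samples)))
  cat(sprintf("descriptors: %d per cell, %d per drug; noise sd %.2f; cluster effect %.2f\n",
              p$p_cell, p$p_drug, p$noise_sd, p$cluster_effect))
  invisible(x)
}

new_partition <- function(train_init, clients, val, holdout, mode, k, seed) {
  structure(list(train_init = train_init, clients = clients, val = val,
                 holdout = holdout, mode = mode, k = k,
                 seed = as.integer(seed)),
            class = "fed_partition")
}

#' @export
print.fed_partition <- function(x, ...) {
  cat(sprintf("Federated partition (%s%s): %d clients\n", x$mode,
              if (!is.null(x$k)) sprintf(", k = %d", x$k) else "",
              length(x$clients)))
  cat(sprintf("  server initial: %d | validation: %d | hold-out: %d | client shares: %s\n",
              length(x$train_init), length(x$val), length(x$holdout),
              paste(lengths(x$clients), collapse = ", ")))
  invisible(x)
}

#' Random client partition of a study
#'
#' Splits sample indices into validation (DV), hold-out (DH) and training
#' (DT) sets; the server keeps an initial fraction of DT, and the remainder
#' is split uniformly at random among the clients.
#'
#' @param study a \code{\link{generate_study}} object (or anything with a
#'   \code{samples} data.frame).
#' @param n_clients number of clients (e.g. 3, 5, 10, 15 or 20).
#' @param fractions named vector: \code{init} = server share of DT (default
#'   0.05), \code{val} and \code{holdout} = shares of all samples (defaults
#'   0.10 each).
#' @param seed integer seed.
#' @return a \code{"fed_partition"} of sample indices.
#' @export
split_random <- function(study, n_clients,
                         fractions = c(init = 0.05, val = 0.10, holdout = 0.10),
                         seed = 1L) {
  n <- nrow(study$samples)
  n_clients <- as.integer(n_clients)
  if (n_clients < 1L) stop_input("n_clients must be >= 1")
  if (fractions[["val"]] + fractions[["holdout"]] >= 1)
    stop_input("validation + holdout fractions must leave room for training")
  with_seed(seed, {
    ord <- sample.int(n)
    n_val <- round(fractions[["val"]] * n)
    n_hold <- round(fractions[["holdout"]] * n)
    val <- ord[seq_len(n_val)]
    holdout <- ord[n_val + seq_len(n_hold)]
    dt <- ord[(n_val + n_hold + 1L):n]
    n_init <- round(fractions[["init"]] * length(dt))
    train_init <- dt[seq_len(n_init)]
    rest <- dt[(n_init + 1L):length(dt)]
    if (length(rest) < n_clients)
      stop_input("a client would receive 0 samples")
    shares <- split(rest, rep_len(seq_len(n_clients), length(rest)))
    new_partition(train_init, unname(shares), val, holdout,
                  mode = "random", k = NULL, seed = seed)
  })
}

#' Drug-clustered (quasi-random) client partition
#'
#' Allocates training samples to clients by drug, with an overlap parameter
#' k = number of distinct drugs per client. With \code{k * n_clients ==
#' n_drugs} (e.g. k = 2, 12 clients, 24 drugs) the client drug sets are a
#' disjoint cover; for larger k each client receives a random sample of k
#' drugs (the allocation is redrawn until every drug is covered, so the
#' client shares always partition the training remainder). When several
#' clients share a drug, that drug's samples are split evenly among them
#' (counts differing by at most 1).
#'
#' @param study a \code{\link{generate_study}} object.
#' @param n_clients number of clients (default 12).
#' @param k drugs per client, \code{2 <= k <= n_drugs}.
#' @param fractions as in \code{\link{split_random}}.
#' @param seed integer seed.
#' @return a \code{"fed_partition"}; clients carry attribute
#'   \code{drug_sets} listing each client's drugs.
#' @export
split_quasi_random <- function(study, n_clients = 12L, k,
                               fractions = c(init = 0.05, val = 0.10,
                                             holdout = 0.10),
                               seed = 1L) {
  n_clients <- as.integer(n_clients); k <- as.integer(k)
  n_drugs <- study$params$n_drugs %||% max(study$samples$drug)
  if (k < 1L || k > n_drugs) stop_input("k must lie in [1, %d]", n_drugs)
  if (n_clients * k < n_drugs)
    stop_input("infeasible: %d clients x %d drugs cannot cover %d drugs",
               n_clients, k, n_drugs)
  base <- split_random(study, n_clients = 1L, fractions = fractions,
                       seed = seed)
  rest <- base$clients[[1L]]
  drug_of <- study$samples$drug
  with_seed(derive_seed(seed, 97L), {
    if (n_clients * k == n_drugs) {
      # disjoint cover: shuffle drugs, deal k to each client
      ds <- split(sample.int(n_drugs), rep(seq_len(n_clients), each = k))
    } else {
      for (try in 1:1000) {
        ds <- replicate(n_clients, sort(sample.int(n_drugs, k)),
                        simplify = FALSE)
        if (length(unique(unlist(ds))) == n_drugs) break
      }
      if (length(unique(unlist(ds))) < n_drugs)
        stop_input("could not cover all drugs with k = %d", k)
    }
    holders <- lapply(seq_len(n_drugs), function(d)
      which(vapply(ds, function(s) d %in% s, TRUE)))
    shares <- replicate(n_clients, integer(0), simplify = FALSE)
    for (d in seq_len(n_drugs)) {
      idx <- rest[drug_of[rest] == d]
      if (!length(idx)) next
      idx <- sample(idx)
      h <- holders[[d]]
      grp <- rep_len(seq_along(h), length(idx))
      for (gi in seq_along(h))
        shares[[h[gi]]] <- c(shares[[h[gi]]], idx[grp == gi])
    }
    part <- new_partition(base$train_init, shares, base$val, base$holdout,
                          mode = "quasi_random", k = k, seed = seed)
    attr(part$clients, "drug_sets") <- lapply(ds, sort)
    part
  })
}

#' Permute a fraction of target values (data-swap corruption)
#'
#' Exactly \code{round(fraction * n)} randomly chosen responses have their
#' values permuted among themselves; features are untouched and the
#' multiset of responses is preserved.
#'
#' @param y numeric response vector of a client's local data.
#' @param fraction fraction of targets to permute, in \eqn{[0, 1]}
#'   (default 0.2).
#' @param seed integer seed.
#' @return corrupted response vector.
#' @export
permute_targets <- function(y, fraction = 0.2, seed = 1L) {
  if (fraction < 0 || fraction > 1) stop_input("fraction must lie in [0, 1]")
  n <- length(y)
  m <- round(fraction * n)
  if (m < 2L) return(y)
  with_seed(seed, {
    idx <- sample.int(n, m)
    y[idx] <- y[sample(idx)]
    y
  })
}

#' Model-ready inputs from a study and fitted feature maps
#'
#' Builds the named input blocks consumed by \code{\link{drf_fit}} /
#' \code{\link{run_federation}}: per-sample flattened cell and drug images
#' under the given feature-to-image maps, or raw concatenated descriptors
#' when \code{maps} is \code{NULL} (the flat ANN representation).
#'
#' @param study a \code{\link{generate_study}} object.
#' @param maps \code{NULL}, or list(cell =, drug =) of
#'   \code{\link{refined_map}} objects.
#' @return list(x = named list of input matrices, y, drug = per-sample drug
#'   label).
#' @export
prepare_inputs <- function(study, maps = NULL) {
  s <- study$samples
  Xc <- study$cell_features[s$cell, , drop = FALSE]
  Xd <- study$drug_features[s$drug, , drop = FALSE]
  x <- if (is.null(maps)) {
    list(x = cbind(Xc, Xd))
  } else {
    list(cell = predict(maps$cell, Xc), drug = predict(maps$drug, Xd))
  }
  list(x = x, y = s$y, drug = s$drug)
}

#' Write study tables and a partition manifest to disk
#'
#' Emits CSV feature/response tables and a JSON manifest of the partition
#' (per-split and per-client sample indices, mode, k, seed).
#'
#' @param study a \code{\link{generate_study}} object.
#' @param partition a partition of the study, or \code{NULL}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, partition = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$cell_features,
                   file.path(dir, "cell_features.csv"), row.names = FALSE)
  utils::write.csv(study$drug_features,
                   file.path(dir, "drug_features.csv"), row.names = FALSE)
  utils::write.csv(study$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  if (!is.null(partition)) {
    jsonlite::write_json(
      list(mode = partition$mode, k = partition$k, seed = partition$seed,
           train_init = partition$train_init, val = partition$val,
           holdout = partition$holdout, clients = partition$clients),
      file.path(dir, "partition.json"), auto_unbox = TRUE, digits = NA,
      null = "null")
  }
  invisible(dir)
}
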