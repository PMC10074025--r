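# Independent oracles used across tests. These re-derive expected values by
# enumeration / direct formula evaluation, never via the package's own
# vectorized code paths.

# recursive enumeration of all root-to-leaf paths of a full binary tree:
# heap node i has children 2i (left, prob s[i]) and 2i+1 (right, 1 - s[i])
oracle_leaf_probs <- function(s, depth) {
  n_internal <- 2^(depth - 1) - 1
  probs <- c()
  walk <- function(node, acc) {
    if (node > n_internal) {
      probs[node - n_internal] <<- acc
      return(invisible())
    }
    walk(2 * node, acc * s[node])
    walk(2 * node + 1, acc * (1 - s[node]))
  }
  walk(1, 1)
  probs
}

oracle_tree_predict <- function(s, mu, depth) {
  sum(oracle_leaf_probs(s, depth) * mu)
}

# total assignment stress, recomputed from scratch
oracle_stress <- function(D, cells, assign_idx) {
  p <- length(assign_idx)
  s <- 0
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    gd <- sqrt(sum((cells[assign_idx[i], ] - cells[assign_idx[j], ])^2))
    s <- s + (D[i, j] - gd)^2
  }
  s
}

# exhaustive-search optimum over all injective assignments of p features
# onto a g x g grid (feasible for p <= 6, g = 3)
oracle_best_stress <- function(D, g) {
  p <- nrow(D)
  cells <- cbind(rep(seq_len(g), each = g), rep(seq_len(g), g))
  n_cells <- g * g
  best <- Inf
  assign_idx <- integer(p)
  used <- rep(FALSE, n_cells)
  rec <- function(i) {
    if (i > p) {
      s <- oracle_stress(D, cells, assign_idx)
      if (s < best) best <<- s
      return(invisible())
    }
    for (c in seq_len(n_cells)) {
      if (used[c]) next
      assign_idx[i] <<- c
      used[c] <<- TRUE
      rec(i + 1)
      used[c] <<- FALSE
    }
  }
  rec(1)
  best
}

# small ready-made regression problem with two image arms
tiny_two_arm_data <- function(n = 60, g = 4, seed = 1) {
  set.seed(seed)
  x <- list(cell = matrix(rnorm(n * g * g), n, g * g),
            drug = matrix(rnorm(n * g * g), n, g * g))
  y <- tanh(x$cell[, 1]) + 0.5 * x$drug[, 2] + rnorm(n, sd = 0.1)
  list(x = x, y = y)
}

# small study + partition used by several federation tests
tiny_partitioned_study <- function(n_cells = 30, n_drugs = 8, seed = 1,
                                   n_clients = 3) {
  study <- generate_study(n_cells = n_cells, n_drugs = n_drugs, p_cell = 9,
                          p_drug = 9, seed = seed)
  part <- split_random(study, n_clients = n_clients, seed = seed + 1)
  inp <- prepare_inputs(study, NULL)
  list(study = study, part = part, inp = inp)
}
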