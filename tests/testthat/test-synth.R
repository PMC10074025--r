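test_that("study generation is seed-reproducible and shaped like the panel", {
  s1 <- generate_study(n_cells = 20, n_drugs = 6, p_cell = 12, p_drug = 8,
                       seed = 4)
  s2 <- generate_study(n_cells = 20, n_drugs = 6, p_cell = 12, p_drug = 8,
                       seed = 4)
  expect_identical(s1, s2)
  expect_equal(dim(s1$cell_features), c(20, 12))
  expect_equal(nrow(s1$samples), 20 * 6)
  expect_true(all(is.finite(s1$samples$y)))
  # default preset mirrors the 504-cell x 24-drug panel
  frm <- formals(generate_study)
  expect_equal(eval(frm$n_cells), 504L)
  expect_equal(eval(frm$n_drugs), 24L)
})

test_that("a flexible model fits noiseless cluster-free data well", {
  study <- generate_study(n_cells = 100, n_drugs = 8, p_cell = 9, p_drug = 9,
                          noise_sd = 0, cluster_effect = 0, seed = 9)
  inp <- prepare_inputs(study, NULL)
  n <- length(inp$y)
  set.seed(1)
  tr <- sample(n, 0.8 * n)
  ctl <- drf_control(preset = "ann", epochs = 200, lr = 0.1, seed = 2,
                     batch_size = 32)
  fit <- drf_fit(lapply(inp$x, function(m) m[tr, , drop = FALSE]),
                 inp$y[tr], ctl, head = "linear")
  yhat <- predict(fit, lapply(inp$x, function(m) m[-tr, , drop = FALSE]))
  expect_lt(nrmse(inp$y[-tr], yhat), 0.2)
})

test_that("random splits partition the sample set with the stated fractions", {
  study <- generate_study(n_cells = 50, n_drugs = 10, p_cell = 6, p_drug = 6,
                          seed = 2)
  n <- nrow(study$samples)
  for (nc in c(1, 3, 5)) {
    part <- split_random(study, n_clients = nc, seed = 7)
    all_idx <- c(part$train_init, part$val, part$holdout,
                 unlist(part$clients))
    expect_setequal(all_idx, seq_len(n))              # disjoint cover
    expect_equal(length(all_idx), n)
    expect_length(part$clients, nc)
    expect_equal(length(part$val), round(0.1 * n))
    dt <- n - length(part$val) - length(part$holdout)
    expect_equal(length(part$train_init), round(0.05 * dt))
  }
  expect_error(split_random(study, n_clients = 10000), "0 samples")
})

test_that("quasi-random splits respect the drug-overlap parameter k", {
  study <- generate_study(n_cells = 40, n_drugs = 24, p_cell = 6, p_drug = 6,
                          seed = 3)
  # k = 2, 12 clients, 24 drugs: pairwise disjoint drug sets covering all
  p2 <- split_quasi_random(study, n_clients = 12, k = 2, seed = 5)
  ds <- attr(p2$clients, "drug_sets")
  expect_true(all(lengths(ds) == 2))
  expect_setequal(unlist(ds), 1:24)
  for (i in 1:11) for (j in (i + 1):12)
    expect_length(intersect(ds[[i]], ds[[j]]), 0)
  # client samples only carry that client's drugs
  for (j in 1:12)
    expect_true(all(study$samples$drug[p2$clients[[j]]] %in% ds[[j]]))
  # full overlap: every client sees every drug
  p24 <- split_quasi_random(study, n_clients = 12, k = 24, seed = 5)
  ds24 <- attr(p24$clients, "drug_sets")
  expect_true(all(vapply(ds24, function(s) identical(s, 1:24), TRUE)))
  # k = 8: per-drug even split, counts differ by <= 1; shares partition DT(-I)
  p8 <- split_quasi_random(study, n_clients = 12, k = 8, seed = 6)
  rest <- setdiff(seq_len(nrow(study$samples)),
                  c(p8$train_init, p8$val, p8$holdout))
  expect_setequal(unlist(p8$clients), rest)
  drug_of <- study$samples$drug
  for (d in 1:24) {
    counts <- vapply(p8$clients, function(idx) sum(drug_of[idx] == d), 0L)
    counts <- counts[counts > 0]
    if (length(counts) > 1) expect_lte(max(counts) - min(counts), 1L)
  }
  expect_error(split_quasi_random(study, n_clients = 2, k = 2, seed = 1),
               "infeasible")
})

test_that("target permutation preserves the multiset and the stated budget", {
  set.seed(8)
  y <- rnorm(100)
  expect_identical(permute_targets(y, 0, seed = 1), y)
  for (s in 1:20) {
    yp <- permute_targets(y, 0.2, seed = s)
    expect_equal(sort(yp), sort(y))
    expect_lte(sum(yp != y), 20)
  }
  yfull <- permute_targets(y, 1, seed = 3)
  expect_equal(sort(yfull), sort(y))
  expect_gt(sum(yfull != y), 80)                      # essentially all moved
  expect_error(permute_targets(y, 1.2), "fraction")
})

test_that("study tables and partition manifest are written to disk", {
  study <- generate_study(n_cells = 10, n_drugs = 4, p_cell = 5, p_drug = 5,
                          seed = 1)
  part <- split_random(study, 2, seed = 2)
  d <- file.path(tempdir(), "fedrf-study-test")
  write_study(study, part, d)
  expect_true(file.exists(file.path(d, "samples.csv")))
  man <- jsonlite::read_json(file.path(d, "partition.json"),
                             simplifyVector = TRUE)
  expect_equal(man$mode, "random")
  expect_setequal(unlist(man$clients), unlist(part$clients))
  unlink(d, recursive = TRUE)
})
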