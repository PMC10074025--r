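test_that("feature distances: identity, symmetry, and the hand-scaled case", {
  X <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(1, 2, 3))
  d <- feature_distance_matrix(X)
  expect_equal(d$matrix["a", "c"], 0)                 # identical columns
  expect_equal(d$matrix["a", "b"], 2)                 # anti-correlated, scaled
  expect_equal(d$matrix, t(d$matrix))
  expect_true(all(diag(d$matrix) == 0))
  expect_true(all(d$matrix >= 0))
  # constant column maps to all-zero standardized column
  Xc <- cbind(u = c(1, 2, 3), v = c(5, 5, 5))
  dc <- feature_distance_matrix(Xc)
  # distance to the zero column is sqrt(sum(z^2)/n) = 1 for a unit-sd column
  expect_equal(dc$matrix["u", "v"], 1)
  expect_error(feature_distance_matrix(matrix(1:3, 3, 1)), "2 features")
  expect_error(feature_distance_matrix(matrix(1:2, 1, 2)), "2 samples")
  # correlation metric bounded in [0, 1]
  dr <- feature_distance_matrix(matrix(rnorm(40), 10, 4), metric = "correlation")
  expect_true(all(dr$matrix >= 0 & dr$matrix <= 1))
})

test_that("metric MDS embedding reproduces exact small configurations", {
  # two points: separation proportional to their distance, deterministic
  d <- structure(list(matrix = matrix(c(0, 3, 3, 0), 2),
                      feature_names = c("a", "b")),
                 class = "feature_distance")
  co <- initial_embedding(d, grid_side = 4)
  expect_equal(sqrt(sum((co[1, ] - co[2, ])^2)), 3, tolerance = 1e-9)
  expect_identical(co, initial_embedding(d, grid_side = 4))
  # unit square: all six pairwise distances recovered up to the common scale
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(sq))
  d4 <- structure(list(matrix = D, feature_names = paste0("f", 1:4)),
                  class = "feature_distance")
  co4 <- initial_embedding(d4, grid_side = 3)
  Dr <- as.matrix(dist(co4))
  ratio <- Dr[lower.tri(Dr)] / D[lower.tri(D)]
  expect_lt(max(abs(ratio - ratio[1])), 1e-6)
  expect_warning(initial_embedding(
    structure(list(matrix = matrix(0, 3, 3), feature_names = letters[1:3]),
              class = "feature_distance"), 5), "degenerate")
})

test_that("pixel assignment is injective, capacity-checked, and stress-decreasing", {
  set.seed(2)
  X <- matrix(rnorm(20 * 12), 20, 12)
  d <- feature_distance_matrix(X)
  co <- initial_embedding(d, 4)
  map <- assign_pixels(co, d, grid_side = 4, seed = 3)
  cell_id <- (map$assignment[, 1] - 1) * 4 + map$assignment[, 2]
  expect_equal(length(unique(cell_id)), 12)           # injective
  expect_true(all(map$assignment >= 1 & map$assignment <= 4))
  expect_lte(map$stress, map$initial_stress + 1e-12)
  expect_error(assign_pixels(co, d, grid_side = 3), "capacity")
  # p = g^2 forces a bijection onto all cells
  X9 <- matrix(rnorm(15 * 9), 15, 9)
  m9 <- refined_map(X9, grid_side = 3, seed = 1)
  ids <- (m9$assignment[, 1] - 1) * 3 + m9$assignment[, 2]
  expect_setequal(ids, 1:9)
})

test_that("hill climb reaches within 10% of the exhaustive optimum (p <= 6, g = 3)", {
  set.seed(14)
  for (rep in 1:4) {
    p <- sample(4:6, 1)
    X <- matrix(rnorm(15 * p), 15, p)
    d <- feature_distance_matrix(X)
    co <- initial_embedding(d, 3)
    map <- assign_pixels(co, d, grid_side = 3, max_iters = 100, seed = rep)
    best <- oracle_best_stress(d$matrix, 3)
    expect_lte(map$stress, best * 1.1 + 1e-9)
    # reported stress agrees with the from-scratch recomputation
    cells <- cbind(map$assignment[, 1], map$assignment[, 2])
    idx <- (map$assignment[, 1] - 1) * 3 + map$assignment[, 2]
    expect_equal(map$stress,
                 oracle_stress(d$matrix, fedrf:::grid_cells(3), idx),
                 tolerance = 1e-10)
  }
})

test_that("image round trip is the identity on assigned cells", {
  set.seed(4)
  X <- matrix(rnorm(30 * 9), 30, 9)
  map <- refined_map(X, grid_side = 3, seed = 2)
  x <- as.numeric(1:9)
  img <- to_image(x, map)
  expect_setequal(as.vector(img), 1:9)               # bijection, no zeros
  expect_equal(img[map$assignment], x)               # exact read-back
  expect_equal(to_image(rep(0, 9), map), matrix(0, 3, 3))
  expect_error(to_image(1:5, map), "does not match")
  # predict() flattening agrees with to_image row-major
  flat <- predict(map, matrix(x, 1))
  expect_equal(matrix(flat, 3, 3, byrow = TRUE), img)
})

test_that("maps serialize to JSON and back unchanged", {
  X <- matrix(rnorm(20 * 7), 20, 7)
  map <- refined_map(X, seed = 9)
  f <- tempfile(fileext = ".json")
  write_refined_map(map, f)
  back <- read_refined_map(f)
  expect_equal(unname(back$assignment), unname(map$assignment))
  expect_equal(back$grid_side, map$grid_side)
  expect_equal(back$stress, map$stress)
  expect_equal(back$feature_names, map$feature_names)
  unlink(f)
})
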