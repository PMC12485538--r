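test_that("graph weights on collinear points match hand evaluation", {
  D <- as.matrix(dist(c(0, 1, 2)))
  nb <- estimate_neighborhoods_layer1(D, kc = 2)
  g <- build_credibility_graph(D, nb, alpha = 2)
  A <- as.matrix(g$A)
  w <- 2 / (1 + exp(0.5))  # gamma = 1/2 under omega_ij = max(omega) = 2
  expect_equal(A[1, 2], w, tolerance = 1e-12)
  expect_equal(A[2, 3], w, tolerance = 1e-12)
  expect_equal(A[1, 3], 0)  # pair not neighbors in either direction
  expect_equal(diag(A), rep(1, 3))
  expect_equal(g$degrees, rowSums(A))
})

test_that("the gamma <= 1 boundary is included", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  nb <- structure(list(neighbors = list(c(1L, 2L), c(2L, 1L)),
                       omega = c(1, 1), sizes = c(2L, 2L),
                       kc = 2L, layer = 1L),
                  class = "gule_neighborhoods")
  g <- build_credibility_graph(D, nb, alpha = 3)
  expect_equal(as.matrix(g$A)[1, 2], 2 / (1 + exp(9 / 2)))
})

test_that("graphs are symmetric, bounded, and weights shrink with alpha", {
  set.seed(21)
  X <- matrix(rnorm(30 * 2), 30, 2)
  D <- compute_distance_matrix(X, "euclidean")
  nb <- estimate_neighborhoods_layer1(D, kc = 5)
  g2 <- build_credibility_graph(D, nb, alpha = 2)
  g6 <- build_credibility_graph(D, nb, alpha = 6)
  A2 <- as.matrix(g2$A)
  A6 <- as.matrix(g6$A)
  expect_symmetric(A2)
  expect_true(all(A2 >= 0 & A2 <= 1))
  off <- row(A2) != col(A2)
  expect_true(all(A6[off] <= A2[off] + 1e-15))
  expect_true(all(g2$degrees > 0))
})

test_that("coincident points get full credibility without division errors", {
  D <- matrix(0, 5, 5)
  nb <- estimate_neighborhoods_layer1(D, kc = 3)
  g <- build_credibility_graph(D, nb, alpha = 9)
  A <- as.matrix(g$A)
  expect_true(all(A[A > 0] == 1))
  s <- estimate_strength(g, nb)
  expect_equal(s, 1)  # complete unit-weight graph saturates the strength
})

test_that("connection strength matches hand evaluation and clipping", {
  D <- as.matrix(dist(c(0, 1, 2)))
  nb <- estimate_neighborhoods_layer1(D, kc = 2)
  g <- build_credibility_graph(D, nb, alpha = 2)
  w <- 2 / (1 + exp(0.5))
  # s_i = (sum_{j != i} a_ij) / (|N_i| - 1): (w, 2w, w) / 1, mean clipped to 1
  expect_equal(mean(c(w, 2 * w, w)) > 1, TRUE)
  expect_equal(estimate_strength(g, nb), 1)
})

test_that("an edgeless graph floors the strength at machine epsilon", {
  D <- matrix(c(0, 5, 5, 0), 2, 2)
  nb <- structure(list(neighbors = list(c(1L, 2L), c(2L, 1L)),
                       omega = c(1, 1), sizes = c(2L, 2L),
                       kc = 2L, layer = 1L),
                  class = "gule_neighborhoods")
  g <- build_credibility_graph(D, nb, alpha = 2)  # gamma = 5 > 1 -> no edge
  expect_warning(s <- estimate_strength(g, nb), "no off-diagonal")
  expect_equal(s, .Machine$double.eps)
  expect_lt(abs(beta_from_strength(s) - 1), 1e-10)
})

test_that("isolated points contribute zero strength with a warning", {
  g <- block_graph(c(3, 3), cross = 0, seed = 4)
  g$sizes[2] <- 1L
  expect_warning(s <- estimate_strength(g), "isolated")
  expect_true(s > 0 && s <= 1)
})

test_that("beta = 1 - s with its limits and domain checks", {
  expect_equal(beta_from_strength(1), 0)
  expect_equal(beta_from_strength(0.4), 0.6)
  expect_equal(beta_from_strength(1e-12), 1 - 1e-12)
  expect_error(beta_from_strength(0), "scalar in")
  expect_error(beta_from_strength(1.2), "scalar in")
})

test_that("self-tuning ablation graph follows the locally scaled Gaussian", {
  set.seed(13)
  X <- matrix(rnorm(20 * 2), 20, 2)
  D <- unclass(compute_distance_matrix(X, "euclidean"))
  g <- selftuning_graph(D, kprime = 7)
  A <- as.matrix(g$A)
  sigma <- vapply(1:20, function(i) sort(D[i, ])[8], 1)
  i <- 1
  j <- order(D[i, ])[2]
  expect_equal(A[i, j], exp(-D[i, j]^2 / (sigma[i] * sigma[j])))
  far <- which.max(D[i, ])
  expect_equal(A[i, far], 0)
  expect_symmetric(A)
})

test_that("graphs export to Matrix-Market and read back identically", {
  g <- block_graph(c(3, 4), seed = 8)
  f <- tempfile(fileext = ".mtx")
  write_graph_mtx(g, f)
  M <- as.matrix(Matrix::readMM(f))
  expect_equal(M, as.matrix(g$A), tolerance = 1e-10)
  unlink(f)
})
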