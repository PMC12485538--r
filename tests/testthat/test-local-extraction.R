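test_that("neighborhood size follows the logarithmic rule with caps", {
  expect_equal(neighborhood_size(1000, 10), 11L)
  expect_equal(neighborhood_size(160, 16), 8L)
  expect_equal(neighborhood_size(14, 7), 6L)   # n = 2K
  expect_equal(neighborhood_size(8, 1), 7L)    # formula gives 8, capped at n-1
  expect_error(neighborhood_size(5, 10), "at least K")
  expect_error(neighborhood_size(10, 2, k0 = 0), "k0")
})

test_that("layer-1 neighborhoods take the kc nearest with index tie-breaks", {
  D <- as.matrix(dist(c(0, 1, 2)))
  nb <- estimate_neighborhoods_layer1(D, kc = 2)
  expect_equal(nb$neighbors[[1]], c(1L, 2L))
  expect_equal(nb$omega[1], 2)
  # middle point ties between its two neighbors -> lower index wins
  expect_equal(nb$neighbors[[2]], c(2L, 1L))
  expect_equal(nb$omega[2], 1)
  expect_equal(nb$neighbors[[3]], c(3L, 2L))
  expect_true(all(nb$sizes == 2L))
  # every point is first in its own ordering
  for (i in 1:3) expect_equal(nb$neighbors[[i]][1], i)
})

test_that("degenerate and capped layer-1 neighborhoods are handled", {
  D0 <- matrix(0, 4, 4)  # all points coincident
  nb <- estimate_neighborhoods_layer1(D0, kc = 2)
  expect_equal(nb$omega, rep(0, 4))
  # kc = n is capped to n - 1 so omega is the farthest distance
  D <- as.matrix(dist(c(0, 1, 2, 4)))
  nb2 <- estimate_neighborhoods_layer1(D, kc = 4)
  expect_equal(nb2$kc, 3L)
  expect_equal(nb2$omega[1], 4)
})

test_that("layer-2 gap rule finds the largest forward gap in the window", {
  # sorted distances from point 1: 0, .01, .02, .03, .9, .91, ...
  x <- c(0, 0.01, 0.02, 0.03, seq(0.9, by = 0.01, length.out = 17))
  D <- as.matrix(dist(x))
  n <- length(x)              # 21; K = 2 -> cap floor(n/K) = 10
  nb <- estimate_neighborhoods_layer2(D, kc = 3, n = n, K = 2)
  expect_equal(nb$sizes[1], 4L)               # gap argmax at j = 4
  expect_equal(nb$neighbors[[1]], 1:4)
  expect_equal(nb$omega[1], 0.9)

  # equal gaps: argmax tie -> smallest j = kc (binary-fraction spacing keeps
  # the gaps exactly equal in floating point)
  xe <- seq(0, 2.5, by = 0.125)
  nbe <- estimate_neighborhoods_layer2(as.matrix(dist(xe)), kc = 3,
                                       n = 21, K = 2)
  expect_equal(nbe$sizes[1], 3L)

  # gap argmax beyond the class-size cap -> ki = floor(n/K)
  xc <- c(seq(0, 0.14, by = 0.01), seq(5, by = 0.01, length.out = 6))
  nbc <- estimate_neighborhoods_layer2(as.matrix(dist(xc)), kc = 3,
                                       n = 21, K = 2)
  expect_equal(nbc$sizes[1], 10L)

  expect_error(estimate_neighborhoods_layer2(D, kc = 21, n = n, K = 2),
               "exceed")
})

test_that("layer-2 sizes always stay within [kc, floor(n/K)]", {
  set.seed(3)
  for (rep in 1:5) {
    X <- matrix(rnorm(40 * 3), 40, 3)
    D <- compute_distance_matrix(X, "cosine")
    nb <- estimate_neighborhoods_layer2(D, kc = 4, K = 4)
    expect_true(all(nb$sizes >= 4L))
    expect_true(all(nb$sizes <= 10L))
  }
})

test_that("alpha defaults depend on average class size and layer", {
  expect_equal(alpha_for_layer(1000, 10, 1), 9)
  expect_equal(alpha_for_layer(1010, 10, 1), 6)
  expect_equal(alpha_for_layer(1000, 10, 2), 2)
  expect_equal(alpha_for_layer(17, 3, 2), 2)
  expect_error(alpha_for_layer(10, 2, 3), "layer")
})

test_that("enhanced credibility matches its closed form and monotonicity", {
  expect_equal(enhanced_credibility(0, 2), 1)
  expect_equal(enhanced_credibility(1, 2), 2 / (1 + exp(2)))
  expect_equal(enhanced_credibility(0.5, 2), 2 / (1 + exp(0.5)))
  # relation to the plain credibility c = exp(-(alpha g)^2 / 2)
  set.seed(9)
  g <- runif(50, 0, 2)
  a <- runif(50, 0.5, 10)
  cc <- exp(-(a * g)^2 / 2)
  expect_equal(mapply(enhanced_credibility, g, a), 2 * cc / (1 + cc))
  # strictly decreasing in gamma and in alpha (for gamma > 0)
  gs <- seq(0, 3, by = 0.1)
  expect_true(all(diff(enhanced_credibility(gs, 3)) < 0))
  as_ <- seq(0.5, 12, by = 0.5)
  vals <- vapply(as_, function(al) enhanced_credibility(0.7, al), 1)
  expect_true(all(diff(vals) < 0))
  expect_true(all(vals > 0 & vals <= 1))
  # overflow guard: enormous alpha*gamma underflows to 0 without warning
  expect_equal(enhanced_credibility(50, 50), 0)
  expect_error(enhanced_credibility(-1, 2), "gamma")
})
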