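test_that("a block-separated graph decomposes with zero perturbation", {
  g <- block_graph(c(4, 4), cross = 0, seed = 1)
  truth <- rep(1:2, each = 4)
  dec <- ideal_decomposition(g, truth, beta = 0.6)
  expect_equal(dec$E, matrix(0, 8, 8), tolerance = 1e-14)
  expect_equal(dec$E_norm2, 0, tolerance = 1e-14)
  expect_equal(dec$rho, rep(0, 8))
  expect_equal(dec$bound, 0)
  expect_equal(dec$epsilon, 0)
  expect_gt(dec$delta_K, 0)
  expect_true(all(dec$connected))
  # U0 columns are unit per-block Perron vectors on the right supports
  expect_equal(colSums(dec$U0^2), c(1, 1), tolerance = 1e-10)
  expect_equal(sum(dec$U0[5:8, 1]^2), 0)
  expect_equal(sum(dec$U0[1:4, 2]^2), 0)
  expect_true(all(dec$U0[1:4, 1] > 0))
})

test_that("the 4-node weak-cross-edge case matches hand evaluation", {
  A <- matrix(0, 4, 4)
  A[1:2, 1:2] <- c(1, 0.8, 0.8, 1)
  A[3:4, 3:4] <- c(1, 0.8, 0.8, 1)
  A[2, 3] <- A[3, 2] <- 0.1
  g <- as_gule_graph(A)
  dec <- ideal_decomposition(g, c(1, 1, 2, 2), beta = 0.5)
  expect_equal(dec$rho, c(0, 0.1 / 1.8, 0.1 / 1.8, 0), tolerance = 1e-12)
  expect_equal(dec$E_norm2, 0.0931156538628, tolerance = 1e-9)
  expect_equal(dec$bound, 0.111803398875, tolerance = 1e-9)
  expect_equal(dec$tau, 1.9 / 1.8, tolerance = 1e-12)
  expect_equal(dec$epsilon, 0.146127434669, tolerance = 1e-9)
  expect_equal(dec$delta_K, 1.192569588, tolerance = 1e-8)
  expect_lte(dec$E_norm2, dec$bound)
})

test_that("beta = 0 reduces rho_beta to raw off-block row sums", {
  g <- block_graph(c(3, 4), cross = 0.2, seed = 2)
  truth <- rep(1:2, c(3, 4))
  dec <- ideal_decomposition(g, truth, beta = 0)
  A <- as.matrix(g$A)
  roff <- rowSums(A) - c(rowSums(A[1:3, 1:3]), rowSums(A[4:7, 4:7]))
  expect_equal(dec$rho_beta, roff, tolerance = 1e-12)
})

test_that("the spectral-norm bound on E holds across random graphs", {
  set.seed(51)
  for (beta in c(0, 0.3, 0.7, 1)) {
    for (rep in 1:10) {
      sizes <- sample(3:6, sample(2:3, 1), replace = TRUE)
      g <- block_graph(sizes, cross = runif(1, 0, 0.4),
                       seed = 1000 * beta + rep)
      truth <- rep.int(seq_along(sizes), sizes)
      dec <- ideal_decomposition(g, truth, beta = beta)
      expect_lte(dec$E_norm2, dec$bound + 1e-12)
    }
  }
})

test_that("the Procrustes-aligned basis obeys the subspace bound", {
  set.seed(52)
  checked <- 0
  for (rep in 1:20) {
    sizes <- c(5, 5)
    g <- block_graph(sizes, cross = runif(1, 0, 0.05), seed = 500 + rep)
    truth <- rep(1:2, each = 5)
    beta <- runif(1)
    dec <- ideal_decomposition(g, truth, beta)
    if (dec$delta_K > 2 * dec$E_norm2) {
      pr <- spectral_project(g, 2, beta)
      Q <- procrustes_rotation(pr$U, dec$U0)
      err <- sqrt(sum((dec$U0 - pr$U %*% Q)^2))
      expect_lte(err, 2 * sqrt(2 * 2) * dec$E_norm2 / dec$delta_K + 1e-10)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 5)
})

test_that("mislabel bound is honest on ideal and perturbed graphs", {
  # ideal case: budget 0, p counts only the exact zeros of the block basis
  g <- block_graph(c(4, 4), cross = 0, seed = 3)
  truth <- rep(1:2, each = 4)
  dec <- ideal_decomposition(g, truth, 0.5)
  pr <- spectral_project(g, 2, 0.5)
  Q <- procrustes_rotation(pr$U, dec$U0)
  Ut <- pr$U %*% Q
  p <- mislabel_bound(dec, Ut)
  expect_equal(p, sum(Ut^2 <= 1e-15))
  expect_equal(clustering_accuracy(cpf_labels(Ut), truth), 1)

  # perturbed graphs: actual mislabels never exceed p
  set.seed(53)
  for (rep in 1:10) {
    g2 <- block_graph(c(5, 5), cross = runif(1, 0.01, 0.08),
                      seed = 700 + rep)
    dec2 <- ideal_decomposition(g2, rep(1:2, each = 5), 0.5)
    if (is.na(dec2$delta_K) || dec2$delta_K <= 0) next
    pr2 <- spectral_project(g2, 2, 0.5)
    Q2 <- procrustes_rotation(pr2$U, dec2$U0)
    p2 <- mislabel_bound(dec2, pr2$U %*% Q2)
    actual <- round((1 - clustering_accuracy(cpf_labels(pr2$U %*% Q2),
                                             rep(1:2, each = 5))) * 10)
    expect_lte(actual, p2)
  }
})

test_that("a vanishing spectral gap returns the undefined-bound sentinel", {
  g <- block_graph(c(4, 4), cross = 0, seed = 4)
  dec <- ideal_decomposition(g, rep(1:2, each = 4), 0.5)
  dec$delta_K <- 0
  expect_warning(p <- mislabel_bound(dec, dec$U0), "delta_K")
  expect_identical(p, Inf)
})

test_that("disconnected class blocks are flagged", {
  A <- diag(6)  # no off-diagonal edges at all: every block disconnected
  A[1, 2] <- A[2, 1] <- 0.5
  g <- as_gule_graph(A)
  expect_warning(dec <- ideal_decomposition(g, rep(1:2, each = 3), 0.5),
                 "disconnected")
  expect_false(all(dec$connected))
})
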