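# Shared fixtures and independent oracles, all built in code.

# Random weighted block graph: `sizes` gives the block sizes; within-block
# off-diagonal weights are drawn from [w_lo, w_hi], cross-block weights from
# [0, cross]; unit self-loops. Returns a gule_graph plus the truth labels.
block_graph <- function(sizes, w_lo = 0.5, w_hi = 1, cross = 0, seed = 1) {
  n <- sum(sizes)
  truth <- rep.int(seq_along(sizes), sizes)
  set.seed(seed)
  A <- matrix(stats::runif(n * n, 0, cross), n, n)
  same <- outer(truth, truth, "==")
  A[same] <- stats::runif(sum(same), w_lo, w_hi)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  as_gule_graph(A, sizes = rep.int(3L, n))
}

as_gule_graph <- function(A, sizes = rep.int(3L, nrow(A)), layer = 1L) {
  As <- methods::as(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                "symmetricMatrix"), "CsparseMatrix")
  structure(list(A = As, degrees = rowSums(A), alpha = NA_real_,
                 layer = layer, sizes = sizes),
            class = "gule_graph")
}

# Brute-force maximizer of the discrete adaptive-cut objective over every
# labeling of n vertices into at most K groups (independent oracle).
brute_force_acut <- function(graph, K, beta) {
  n <- nrow(graph$A)
  best <- -Inf
  best_lab <- NULL
  lab <- integer(n)
  total <- K^n
  for (code in 0:(total - 1L)) {
    x <- code
    for (i in seq_len(n)) {
      lab[i] <- x %% K + 1L
      x <- x %/% K
    }
    sc <- acut_objective(graph, lab, beta)
    if (sc > best + 1e-12) {
      best <- sc
      best_lab <- lab
    }
  }
  list(score = best, labels = best_lab)
}

# Brute-force clustering accuracy over all permutations of predicted labels
# (independent of the Hungarian path).
brute_force_acc <- function(pred, truth) {
  ks <- sort(unique(c(pred, truth)))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_along(ks))) {
    mapped <- ks[p][match(pred, ks)]
    best <- max(best, mean(mapped == truth))
  }
  best
}

# Ideal nonnegative two-block basis with orthonormal columns.
ideal_block_basis <- function(sizes) {
  n <- sum(sizes)
  K <- length(sizes)
  U0 <- matrix(0, n, K)
  at <- 0L
  for (k in seq_len(K)) {
    idx <- at + seq_len(sizes[k])
    v <- abs(stats::rnorm(sizes[k])) + 0.2
    U0[idx, k] <- v / sqrt(sum(v^2))
    at <- at + sizes[k]
  }
  U0
}

random_orthogonal_test <- function(K) qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))

# all permutations of 1..n as rows of a matrix
gtools_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- gtools_perms(n - 1L)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
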