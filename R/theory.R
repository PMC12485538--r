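# spectral (2-)norm of a symmetric matrix
sym_norm2 <- function(M) {
  if (!length(M)) return(0)
  max(abs(eigen(as.matrix(M), symmetric = TRUE, only.values = TRUE)$values))
}

# connected components of a symmetric adjacency (BFS on nonzeros)
adjacency_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] == 0L) {
      cur <- cur + 1L
      queue <- start
      comp[start] <- cur
      while (length(queue)) {
        i <- queue[[1L]]
        queue <- queue[-1L]
        nbrs <- which(A[i, ] > 0 & comp == 0L)
        comp[nbrs] <- cur
        queue <- c(queue, nbrs)
      }
    }
  }
  comp
}

#' Ideal block decomposition of a rescaled credibility graph
#'
#' Splits the rescaled graph `G = D^{-beta/2} A D^{-beta/2}` into an ideal
#' block-diagonal part `G0` and a perturbation `E = G - G0`. Crucially, each
#' diagonal block of `G0` is rescaled by its *own* within-class row sums
#' (`Gbar_kk = Dbar_k^{-beta/2} A_kk Dbar_k^{-beta/2}`), not by the global
#' degrees. The decomposition carries everything the perturbation analysis
#' needs:
#' * `rho` / `rho_beta`: per-point off-block row sums divided by within-block
#'   row sums (raised to `beta` for `rho_beta`);
#' * `bound = (1 + beta) * max(rho_beta)`: the proven upper bound on
#'   `||E||_2`;
#' * `tau`: the largest ratio of any two total row sums of `A`;
#' * `epsilon = beta * ||rho||_2 + tau^{beta/2} * ||rho_beta||_2`;
#' * `U0`: the ideal basis whose k-th column is the Perron vector of
#'   `Gbar_kk` placed on class k's indices (blocks with several connected
#'   components are flagged);
#' * `delta_K`: the gap between the K-th and (K+1)-th eigenvalues of `G0`.
#'
#' @param graph `gule_graph`.
#' @param truth integer class labels covering all points.
#' @param beta rescaling exponent.
#' @return object of class `gule_decomposition`.
#' @export
ideal_decomposition <- function(graph, truth, beta) {
  A <- as.matrix(graph$A)
  n <- nrow(A)
  truth <- as.integer(truth)
  if (length(truth) != n) stop("truth must cover all points")
  classes <- sort(unique(truth))
  K <- length(classes)
  r <- rowSums(A)
  G <- diag(r^(-beta / 2)) %*% A %*% diag(r^(-beta / 2))

  G0 <- matrix(0, n, n)
  rho <- numeric(n)
  rho_beta <- numeric(n)
  U0 <- matrix(0, n, K)
  connected <- logical(K)
  for (k in seq_len(K)) {
    idx <- which(truth == classes[k])
    Akk <- A[idx, idx, drop = FALSE]
    rin <- rowSums(Akk)
    roff <- r[idx] - rin
    if (any(rin == 0)) {
      stop("class ", classes[k], " has point(s) with zero internal weight")
    }
    rho[idx] <- roff / rin
    rho_beta[idx] <- roff / rin^beta
    Gkk <- diag(rin^(-beta / 2)) %*% Akk %*% diag(rin^(-beta / 2))
    G0[idx, idx] <- Gkk
    comp <- adjacency_components(Akk)
    connected[k] <- max(comp) == 1L
    ev <- eigen(Gkk, symmetric = TRUE)
    perron <- fix_eigvec_signs(ev$vectors[, 1L, drop = FALSE])[, 1L]
    U0[idx, k] <- perron
  }
  if (any(!connected)) {
    warning("class block(s) ",
            paste(classes[!connected], collapse = ", "),
            " are disconnected; their Perron vectors live on the dominant ",
            "connected sub-block")
  }

  E <- G - G0
  tau <- max(r) / min(r)
  eps <- beta * sqrt(sum(rho^2)) + tau^(beta / 2) * sqrt(sum(rho_beta^2))
  ev0 <- eigen(G0, symmetric = TRUE, only.values = TRUE)$values
  delta_K <- if (n > K) ev0[K] - ev0[K + 1L] else NA_real_

  structure(list(G = G, G0 = G0, E = E, E_norm2 = sym_norm2(E),
                 rho = rho, rho_beta = rho_beta,
                 bound = (1 + beta) * max(rho_beta),
                 tau = tau, epsilon = eps,
                 U0 = U0, delta_K = delta_K, eigvals_G0 = ev0,
                 beta = beta, classes = classes, connected = connected),
            class = "gule_decomposition")
}

#' @method print gule_decomposition
#' @export
print.gule_decomposition <- function(x, ...) {
  cat("Ideal block decomposition (beta = ", format(round(x$beta, 4)),
      ")\n", sep = "")
  cat(sprintf("  ||E||_2 = %.4g  <=  bound (1+beta) max(rho_beta) = %.4g\n",
              x$E_norm2, x$bound))
  cat(sprintf("  delta_K = %.4g, epsilon = %.4g, tau = %.4g\n",
              x$delta_K, x$epsilon, x$tau))
  if (any(!x$connected)) {
    cat("  disconnected class block(s): ",
        paste(x$classes[!x$connected], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Orthogonal Procrustes alignment
#'
#' The orthogonal `Q` minimizing `||U0 - U Q||_F`, from the SVD of
#' `U' U0`.
#'
#' @param U,U0 n x K matrices.
#' @return K x K orthogonal matrix.
#' @export
procrustes_rotation <- function(U, U0) {
  sv <- svd(crossprod(U, U0))
  sv$u %*% t(sv$v)
}

#' Worst-case mislabel count from the perturbation budget
#'
#' Sorting all squared entries of the rotated basis ascending, `p` is the
#' largest count whose prefix sum stays within the budget
#' `8 epsilon^2 / delta_K^2`: at most `p` points can be misclustered by the
#' absolute-argmax labeling. Returns `Inf` (with a warning) when
#' `delta_K <= 0`, where the bound is undefined.
#'
#' @param dec `gule_decomposition`.
#' @param Utilde rotated eigenbasis (e.g. the Procrustes-aligned `U Q`).
#' @return integer bound `p` (possibly 0), or `Inf`.
#' @export
mislabel_bound <- function(dec, Utilde) {
  if (is.na(dec$delta_K) || dec$delta_K <= 0) {
    warning("delta_K <= 0: mislabel bound undefined, returning Inf")
    return(Inf)
  }
  budget <- 8 * dec$epsilon^2 / dec$delta_K^2
  eta2 <- sort(as.vector(as.matrix(Utilde)^2))
  sum(cumsum(eta2) <= budget + 1e-15)
}
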