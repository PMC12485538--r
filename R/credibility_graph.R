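#' Build the symmetric credibility graph
#'
#' For every unordered pair with `j` in `N(i)` or `i` in `N(j)`, the
#' pair-level exclusion radius is `omega_ij = max(omega_i, omega_j)`, the
#' normalized distance is `gamma_ij = d(i, j) / omega_ij` (defined as 0 for
#' coincident points with `omega_ij = 0`), and the edge weight is the
#' enhanced credibility `2 / (1 + exp((alpha * gamma_ij)^2 / 2))` when
#' `gamma_ij <= 1` (boundary included) and 0 otherwise. Self-loops carry
#' `a_ii = 1` (`gamma_ii = 0`), so every degree is positive.
#'
#' @param D distance matrix consistent with `nb`.
#' @param nb `gule_neighborhoods` from the same points.
#' @param alpha credibility parameter.
#' @return an object of class `gule_graph`: sparse symmetric adjacency `A`
#'   (entries in \[0, 1\]), `degrees` (self-loops included), `alpha`, `layer`,
#'   and the neighborhood `sizes`.
#' @export
build_credibility_graph <- function(D, nb, alpha) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!inherits(nb, "gule_neighborhoods")) stop("nb must be gule_neighborhoods")
  if (length(nb$neighbors) != n) stop("neighborhood set inconsistent with D")
  if (all(lengths(nb$neighbors) == 0L)) stop("empty neighborhood set")

  ii <- rep.int(seq_len(n), vapply(nb$neighbors, length, 1L) - 1L)
  jj <- unlist(lapply(nb$neighbors, `[`, -1L), use.names = FALSE)
  # unordered pairs, deduplicated across the two directions
  lo <- pmin(ii, jj)
  hi <- pmax(ii, jj)
  keep <- !duplicated(lo + n * hi)
  lo <- lo[keep]
  hi <- hi[keep]

  d <- D[cbind(lo, hi)]
  omegaij <- pmax(nb$omega[lo], nb$omega[hi])
  gamma <- ifelse(d <= 0, 0, ifelse(omegaij <= 0, Inf, d / omegaij))
  w <- enhanced_credibility(pmin(gamma, 1), alpha)
  w[gamma > 1] <- 0

  nz <- w > 0
  A <- Matrix::sparseMatrix(i = lo[nz], j = hi[nz], x = w[nz],
                            dims = c(n, n), symmetric = TRUE)
  A <- A + Matrix::Diagonal(n)
  A <- methods::as(methods::as(A, "symmetricMatrix"), "CsparseMatrix")
  structure(list(A = A, degrees = Matrix::rowSums(A), alpha = alpha,
                 layer = nb$layer, sizes = nb$sizes),
            class = "gule_graph")
}

#' Average connection strength of a credibility graph
#'
#' Per point, `s_i` is the sum of its off-diagonal edge weights (every edge
#' of the symmetric graph, including those gained by symmetrization) divided
#' by `|N(i)| - 1`; the graph's strength `s` is the mean of the `s_i`,
#' clipped to (0, 1]. A point with `|N(i)| = 1` contributes `s_i = 0` with a
#' warning; a graph with no off-diagonal edge mass is floored at machine
#' epsilon with a warning.
#'
#' @param graph `gule_graph`.
#' @param nb the `gule_neighborhoods` the graph was built from (for the
#'   neighborhood sizes); defaults to the sizes stored in the graph.
#' @return scalar `s` in (0, 1].
#' @export
estimate_strength <- function(graph, nb = NULL) {
  sizes <- if (is.null(nb)) graph$sizes else nb$sizes
  offdeg <- graph$degrees - Matrix::diag(graph$A)
  si <- numeric(length(offdeg))
  pos <- sizes >= 2L
  if (any(!pos)) {
    warning(sum(!pos), " isolated point(s) with |N(i)| = 1 contribute s_i = 0")
  }
  si[pos] <- offdeg[pos] / (sizes[pos] - 1)
  s <- mean(si)
  if (s <= 0) {
    warning("graph has no off-diagonal edge mass; ",
            "strength floored at machine epsilon")
    s <- .Machine$double.eps
  }
  min(s, 1)
}

#' Adaptive cut exponent from connection strength
#'
#' `beta = 1 - s`: dense graphs (s near 1) give beta near 0, the ratio
#' association limit; sparse graphs (s near 0) give beta near 1, the
#' normalized cut limit.
#'
#' @param s average connection strength in (0, 1].
#' @return beta in \[0, 1).
#' @export
beta_from_strength <- function(s) {
  if (!is.numeric(s) || length(s) != 1L || is.na(s) || s <= 0 || s > 1) {
    stop("s must be a scalar in (0, 1]")
  }
  1 - s
}

#' Self-tuning Gaussian similarity graph (ablation)
#'
#' The locally scaled Gaussian affinity `s_ij = exp(-d(i,j)^2 / (sigma_i
#' sigma_j))` for `d(i,j) < max(sigma_i, sigma_j)` with `sigma_i` the
#' distance of point i to its k'-th nearest neighbor, and `s_ii = 0`.
#' Provided as a swap-in alternative to the credibility graph for ablation
#' studies. A unit self-loop is added when a row would otherwise have zero
#' degree, so degree rescaling stays defined.
#'
#' @param D distance matrix.
#' @param kprime local scale neighbor index (default 7).
#' @return `gule_graph` (with `sizes` set to `kprime` per point).
#' @export
selftuning_graph <- function(D, kprime = 7L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (kprime + 1L > n) stop("kprime + 1 exceeds n")
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    ord <- neighbor_order(D[i, ], i)
    sigma[i] <- D[i, ord[kprime + 1L]]  # k'-th closest excluding self
  }
  S <- exp(-D^2 / tcrossprod(sigma))
  S[D >= outer(sigma, sigma, pmax)] <- 0
  diag(S) <- 0
  iso <- rowSums(S) == 0
  diag(S)[iso] <- 1
  A <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE),
                               "symmetricMatrix"), "CsparseMatrix")
  structure(list(A = A, degrees = Matrix::rowSums(A), alpha = NA_real_,
                 layer = 1L, sizes = rep.int(as.integer(kprime), n)),
            class = "gule_graph")
}

#' @method print gule_graph
#' @export
print.gule_graph <- function(x, ...) {
  n <- nrow(x$A)
  nnz <- Matrix::nnzero(x$A) - n  # off-diagonal
  cat("Credibility graph: ", n, " vertices, ", nnz, " off-diagonal nonzeros",
      " (alpha = ", format(x$alpha), ")\n", sep = "")
  invisible(x)
}

#' Export a credibility graph as a Matrix-Market file
#'
#' @param graph `gule_graph`.
#' @param path output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_graph_mtx <- function(graph, path) {
  Matrix::writeMM(methods::as(graph$A, "generalMatrix"), path)
  invisible(path)
}
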