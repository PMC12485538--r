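#' Degree-rescaled adjacency
#'
#' Returns `D^{-beta/2} A D^{-beta/2}` with `D = diag(degrees)`. At
#' `beta = 0` this is `A` itself (ratio association limit); at `beta = 1` it
#' is the standard normalized affinity (normalized cut limit).
#'
#' @param graph `gule_graph` (or a list with elements `A` and `degrees`).
#' @param beta rescaling exponent in \[0, 1\].
#' @return sparse symmetric matrix.
#' @export
rescale_graph <- function(graph, beta) {
  if (any(graph$degrees <= 0)) stop("zero degree: graph must have self-loops")
  sc <- graph$degrees^(-beta / 2)
  S <- Matrix::Diagonal(x = sc)
  G <- S %*% graph$A %*% S
  methods::as(methods::as(G, "symmetricMatrix"), "CsparseMatrix")
}

# Deterministic sign convention: orient each column so its largest-magnitude
# entry (ties -> lowest index) is positive.
fix_eigvec_signs <- function(U) {
  for (k in seq_len(ncol(U))) {
    m <- which.max(abs(U[, k]))
    if (U[m, k] < 0) U[, k] <- -U[, k]
  }
  U
}

#' Spectral projection of a credibility graph
#'
#' Computes the `K` eigenvectors of the rescaled graph
#' `D^{-beta/2} A D^{-beta/2}` belonging to its `K` algebraically largest
#' eigenvalues; the rows of the resulting orthonormal basis `U` are the
#' projected points. A dense symmetric eigendecomposition is used — exact,
#' deterministic, and fast at the scales this package targets (thousands of
#' points). `K + 1` leading eigenvalues are returned so the spectral gap
#' `delta_K = lambda_K - lambda_{K+1}` is available.
#'
#' @param graph `gule_graph`.
#' @param K number of classes (`K < n`).
#' @param beta rescaling exponent.
#' @return object of class `gule_projection`: `U` (n x K, deterministic
#'   column signs), `eigvals` (length `min(K + 1, n)`, descending), `beta`,
#'   `gap`.
#' @export
spectral_project <- function(graph, K, beta) {
  n <- nrow(graph$A)
  if (K >= n) stop("K must be smaller than the number of points")
  G <- as.matrix(rescale_graph(graph, beta))
  ee <- eigen(G, symmetric = TRUE)  # eigenvalues in decreasing order
  m <- min(K + 1L, n)
  U <- fix_eigvec_signs(ee$vectors[, seq_len(K), drop = FALSE])
  eigvals <- ee$values[seq_len(m)]
  gap <- if (m > K) eigvals[K] - eigvals[K + 1L] else NA_real_
  structure(list(U = U, eigvals = eigvals, beta = beta, gap = gap),
            class = "gule_projection")
}

#' @method print gule_projection
#' @export
print.gule_projection <- function(x, ...) {
  cat("Spectral projection: ", nrow(x$U), " points x ", ncol(x$U),
      " dimensions (beta = ", format(round(x$beta, 4)), ")\n", sep = "")
  cat("  leading eigenvalues: ",
      paste(format(round(x$eigvals, 4)), collapse = ", "), "\n", sep = "")
  if (!is.na(x$gap)) cat("  spectral gap delta_K: ",
                         format(signif(x$gap, 4)), "\n", sep = "")
  invisible(x)
}

#' Discrete adaptive-cut objective
#'
#' The discrete score `sum_k (sum_{i,j in C_k} a_ij) / (sum_{t in C_k}
#' d_t^beta)` of a labeling, used for brute-force verification of the
#' spectral relaxation. Diagonal entries (self-loops) are included in both
#' the within-class weight and the degrees.
#'
#' @param graph `gule_graph`.
#' @param labels integer labels partitioning all vertices; every referenced
#'   class must be nonempty.
#' @param beta rescaling exponent.
#' @return scalar score.
#' @export
acut_objective <- function(graph, labels, beta) {
  n <- nrow(graph$A)
  if (length(labels) != n) stop("labels must cover all vertices")
  A <- as.matrix(graph$A)
  d <- graph$degrees
  score <- 0
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    if (!length(idx)) stop("empty class ", k)
    score <- score + sum(A[idx, idx, drop = FALSE]) / sum(d[idx]^beta)
  }
  score
}
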