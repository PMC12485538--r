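#' Pairwise distance matrix under a named metric
#'
#' Computes the symmetric matrix of pairwise dissimilarities between the rows
#' of a feature matrix. Supported metrics are `euclidean` (L2), `cosine`
#' (1 minus the cosine of the angle between sample vectors), `correlation`
#' (1 minus the Pearson correlation across features) and `spearman` (1 minus
#' the Spearman rank correlation, midrank ties). The cosine-family metrics are
#' bounded in \[0, 2\].
#'
#' @param X numeric matrix, rows = samples, columns = features.
#' @param metric one of `"euclidean"`, `"cosine"`, `"correlation"`,
#'   `"spearman"`.
#' @return an object of class `gule_dist`: the n x n distance matrix with
#'   attribute `metric`. Diagonal entries are exactly zero.
#' @export
#' @examples
#' X <- matrix(rnorm(20), 5, 4)
#' D <- compute_distance_matrix(X, "cosine")
#' max(abs(D - t(D)))  # 0
compute_distance_matrix <- function(X,
                                    metric = c("euclidean", "cosine",
                                               "correlation", "spearman")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be a numeric matrix")
  if (anyNA(X)) stop("X contains missing values; impute or drop them first")
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")

  D <- switch(metric,
    euclidean = as.matrix(stats::dist(X, method = "euclidean")),
    cosine = {
      nrm <- sqrt(rowSums(X^2))
      bad <- which(nrm == 0)
      if (length(bad)) {
        stop("cosine distance undefined for all-zero row(s): ",
             paste(bad, collapse = ", "))
      }
      1 - tcrossprod(X / nrm)
    },
    correlation = {
      sds <- apply(X, 1L, stats::sd)
      bad <- which(sds == 0)
      if (length(bad)) {
        stop("correlation distance undefined for constant row(s): ",
             paste(bad, collapse = ", "))
      }
      1 - stats::cor(t(X))
    },
    spearman = {
      R <- t(apply(X, 1L, rank))  # midrank ties
      sds <- apply(R, 1L, stats::sd)
      bad <- which(sds == 0)
      if (length(bad)) {
        stop("spearman distance undefined for constant-rank row(s): ",
             paste(bad, collapse = ", "))
      }
      1 - stats::cor(t(R))
    })

  # numerical guards: exact symmetry, zero diagonal, clamp to valid range
  D <- (D + t(D)) / 2
  dimnames(D) <- NULL
  diag(D) <- 0
  D[D < 0] <- 0
  if (metric != "euclidean") D[D > 2] <- 2
  structure(D, metric = metric, class = c("gule_dist", "matrix", "array"))
}

#' Cosine distances between rows, tolerating all-zero rows
#'
#' Internal variant used for projected points: an all-zero row has undefined
#' direction, so its distance to every other point is set to the metric's
#' upper bound 2 (with a warning) and 0 to itself.
#' @noRd
cosine_distance_safe <- function(X) {
  X <- as.matrix(X)
  nrm <- sqrt(rowSums(X^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero row(s) in projected points; ",
            "their cosine distances are set to the maximum (2)")
    nrm[zero] <- 1
  }
  D <- 1 - tcrossprod(X / nrm)
  if (any(zero)) {
    D[zero, ] <- 2
    D[, zero] <- 2
  }
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D[D < 0] <- 0
  D[D > 2] <- 2
  structure(D, metric = "cosine", class = c("gule_dist", "matrix", "array"))
}

#' Mean pairwise-NMI consensus scores of a set of labelings
#'
#' Given one labeling per candidate distance metric, scores each candidate by
#' the mean normalized mutual information of its labeling against every other
#' candidate's labeling. The winner is the candidate with the highest mean
#' score; exact ties are broken by candidate order.
#'
#' @param labelings named list of integer label vectors (same length).
#' @return list with `scores` (named numeric), `winner` (name), and the full
#'   pairwise `nmi` matrix.
#' @export
consensus_scores <- function(labelings) {
  m <- length(labelings)
  if (m < 2L) stop("need at least 2 labelings to form a consensus")
  nms <- names(labelings)
  if (is.null(nms)) nms <- paste0("metric", seq_len(m))
  C <- matrix(1, m, m, dimnames = list(nms, nms))
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      C[a, b] <- C[b, a] <- nmi(labelings[[a]], labelings[[b]])
    }
  }
  scores <- (rowSums(C) - 1) / (m - 1)
  names(scores) <- nms
  winner <- nms[which.max(scores)]  # first max = candidate order tie-break
  list(scores = scores, winner = winner, nmi = C)
}

#' Consensus-based selection of a distance metric
#'
#' Runs the full two-layer clustering once per candidate metric and selects
#' the metric whose labeling agrees best, on average (mean pairwise NMI),
#' with the labelings produced under the other candidates. No ground-truth
#' labels are needed. A candidate whose pipeline run fails is excluded with a
#' warning; if fewer than two candidates survive, the selection aborts.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param K number of classes.
#' @param candidates character vector of metric names (>= 2).
#' @param ... further arguments passed to [gule()] (e.g. `seed`, `k0`).
#' @return list with `metric` (the winner), `scores`, `nmi` matrix and the
#'   per-candidate `labelings`.
#' @export
consensus_select_metric <- function(X, K,
                                    candidates = c("euclidean", "cosine",
                                                   "correlation", "spearman"),
                                    ...) {
  if (length(candidates) < 2L) stop("need at least 2 candidate metrics")
  labelings <- list()
  for (m in candidates) {
    fit <- tryCatch(gule(X, K, metric = m, ...), error = function(e) e)
    if (inherits(fit, "error")) {
      warning("metric '", m, "' excluded from consensus: ",
              conditionMessage(fit))
    } else {
      labelings[[m]] <- fit$labels
    }
  }
  if (length(labelings) < 2L) {
    stop("fewer than 2 candidate metrics produced a labeling; ",
         "cannot form a consensus")
  }
  cs <- consensus_scores(labelings)
  list(metric = cs$winner, scores = cs$scores, nmi = cs$nmi,
       labelings = labelings)
}
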