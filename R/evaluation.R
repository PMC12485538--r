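# Minimum-cost perfect matching on a square cost matrix (Hungarian method,
# shortest-augmenting-path formulation, O(n^3)). Returns, for each row, its
# assigned column. Validated against brute-force permutation in the tests.
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  virt <- n + 1L  # virtual column starting each augmentation
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j]: row currently matched to column j (0 = free)
  way <- integer(n)
  for (i in seq_len(n)) {
    p[virt] <- i
    j0 <- virt
    minv <- rep(Inf, n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == virt) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j]] <- j
  assignment
}

# contingency table of two labelings (rows = first argument)
label_table <- function(a, b) {
  table(factor(a, levels = sort(unique(a))),
        factor(b, levels = sort(unique(b))))
}

#' Clustering accuracy under optimal class matching
#'
#' The maximum fraction of agreeing samples over all one-to-one matchings of
#' predicted to true classes, found by optimal assignment on the confusion
#' matrix. Invariant to relabeling of either argument; always at least
#' `1 / K`.
#'
#' @param pred,truth equal-length label vectors.
#' @return ACC in \[0, 1\].
#' @export
#' @examples
#' clustering_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
clustering_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  if (!length(pred)) stop("empty labelings")
  tab <- unclass(label_table(truth, pred))
  m <- max(dim(tab))
  cm <- matrix(0, m, m)
  cm[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  assignment <- hungarian_min(max(cm) - cm)
  sum(cm[cbind(seq_len(m), assignment)]) / length(pred)
}

#' Confusion matrix of two labelings
#'
#' @param truth,pred equal-length label vectors; rows of the result are the
#'   true classes, columns the predicted clusters.
#' @return integer count matrix.
#' @export
confusion_matrix <- function(truth, pred) {
  if (length(pred) != length(truth)) stop("length mismatch")
  unclass(label_table(truth, pred))
}

#' Normalized mutual information
#'
#' Mutual information of the two labelings normalized by the arithmetic mean
#' of their entropies, `2 I / (H1 + H2)`. A constant labeling carries no
#' information and scores 0 (two identical constant labelings score 1).
#'
#' @param a,b equal-length label vectors.
#' @return NMI in \[0, 1\].
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  tab <- unclass(label_table(a, b)) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  nzr <- tab > 0
  I <- sum(tab[nzr] * log(tab[nzr] / outer(pa, pb)[nzr]))
  Ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  Hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (Ha + Hb == 0) return(1)  # both constant: trivially identical partitions
  max(0, min(1, 2 * I / (Ha + Hb)))
}

#' Adjusted Rand index
#'
#' The Rand index corrected for chance under the permutation model; 1 for
#' identical partitions, about 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return ARI in (-1, 1\].
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  n <- length(a)
  tab <- unclass(label_table(a, b))
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  mx <- (sa + sb) / 2
  if (mx == expected) return(if (sij == expected) 1 else 0)
  (sij - expected) / (mx - expected)
}

#' Internal clustering indices
#'
#' Three label-quality measures that need no ground truth beyond the
#' labeling itself:
#' * `silhouette`: mean silhouette width over all points (via
#'   [cluster::silhouette()]); `NA` when only one class is present.
#' * `neighborhood_purity`: mean over points of the fraction of their
#'   estimated neighbors (excluding the point itself) sharing the point's
#'   label; needs `neighborhoods`.
#' * `graph_score`: within-class off-diagonal edge weight divided by total
#'   off-diagonal edge weight; needs `graph`. Equals 1 exactly when no
#'   inter-class edge carries weight.
#'
#' @param labels integer label vector.
#' @param D distance matrix (for the silhouette); alternatively give `X` and
#'   euclidean distances are computed.
#' @param X feature matrix, used only when `D` is missing.
#' @param graph optional `gule_graph` for the graph score.
#' @param neighborhoods optional `gule_neighborhoods` for the purity.
#' @return named list with the available indices (`NA` where inputs are
#'   missing or undefined).
#' @export
internal_indices <- function(labels, D = NULL, X = NULL, graph = NULL,
                             neighborhoods = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)

  sil <- NA_real_
  if (is.null(D) && !is.null(X)) D <- compute_distance_matrix(X, "euclidean")
  if (!is.null(D)) {
    if (length(unique(labels)) < 2L) {
      sil <- NA_real_  # undefined for a single class
    } else if (all(tabulate(labels) <= 1L)) {
      sil <- 0  # every cluster a singleton: zero width by convention
    } else {
      sw <- cluster::silhouette(labels, dmatrix = as.matrix(D))
      sil <- mean(sw[, "sil_width"])
    }
  }

  np <- NA_real_
  if (!is.null(neighborhoods)) {
    fr <- vapply(seq_len(n), function(i) {
      nbrs <- setdiff(neighborhoods$neighbors[[i]], i)
      if (!length(nbrs)) return(1)
      mean(labels[nbrs] == labels[i])
    }, 1)
    np <- mean(fr)
  }

  gs <- NA_real_
  if (!is.null(graph)) {
    A <- as.matrix(graph$A)
    diag(A) <- 0
    total <- sum(A)
    if (total > 0) {
      within <- sum(A * outer(labels, labels, `==`))
      gs <- within / total
    }
  }

  list(silhouette = sil, neighborhood_purity = np, graph_score = gs)
}

#' Evaluate a predicted labeling against ground truth
#'
#' Convenience wrapper collecting ACC, NMI, ARI and the confusion matrix.
#'
#' @param pred,truth equal-length label vectors.
#' @return list with `acc`, `nmi`, `ari`, `confusion`.
#' @export
evaluate_labels <- function(pred, truth) {
  list(acc = clustering_accuracy(pred, truth),
       nmi = nmi(pred, truth),
       ari = ari(pred, truth),
       confusion = confusion_matrix(truth, pred))
}
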