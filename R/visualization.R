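#' Coupled distance matrix for topology-preserving embedding
#'
#' The convex combination of the normalized raw-data distances and the
#' cosine distances of the projected points:
#' `lambda * D_raw / max(D_raw) + (1 - lambda) * D_cos(U) / 2`. Both terms
#' lie in \[0, 1\] (the cosine term is divided by its range bound 2). The
#' projection term suppresses inter-class proximity, so embeddings of the
#' coupled matrix separate classes while the raw term preserves each class's
#' internal topology.
#'
#' @param Draw raw-data distance matrix.
#' @param U spectral projection (a `gule_projection` or its `U` matrix).
#' @param lambda weight on the raw term, in \[0, 1\] (default 0.5).
#' @return symmetric matrix with zero diagonal and entries in \[0, 1\],
#'   with attributes `lambda`.
#' @export
coupled_distance <- function(Draw, U, lambda = 0.5) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  Draw <- as.matrix(Draw)
  mx <- max(Draw)
  if (mx == 0) stop("all raw distances are zero; cannot normalize")
  if (inherits(U, "gule_projection")) U <- U$U
  if (nrow(U) != nrow(Draw)) stop("U and Draw disagree on n")
  Dc <- cosine_distance_safe(U)
  out <- lambda * (Draw / mx) + (1 - lambda) * (unclass(Dc) / 2)
  out <- (out + t(out)) / 2
  diag(out) <- 0
  structure(out, lambda = lambda)
}

#' 2-D embedding of a precomputed distance matrix
#'
#' Hands a (coupled) distance matrix to an embedding backend. `"tsne"`
#' requires the `Rtsne` package and `"umap"` the `uwot` package (both called
#' with the matrix declared as precomputed distances); `"mds"` uses
#' classical multidimensional scaling ([stats::cmdscale()]), which is always
#' available and fully deterministic. The seed is forwarded to the
#' stochastic backends.
#'
#' @param D symmetric distance matrix.
#' @param method `"mds"`, `"tsne"` or `"umap"`.
#' @param seed integer seed for stochastic backends.
#' @param ... passed to the backend.
#' @return n x 2 coordinate matrix.
#' @export
embed_coords <- function(D, method = c("mds", "tsne", "umap"), seed = 0L,
                         ...) {
  method <- match.arg(method)
  D <- as.matrix(D)
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  n <- nrow(D)
  if (method == "mds") {
    Y <- stats::cmdscale(D, k = 2L)
    if (ncol(Y) < 2L) Y <- cbind(Y, 0)[, 1:2, drop = FALSE]
    return(unname(Y))
  }
  if (method == "tsne") {
    if (!requireNamespace("Rtsne", quietly = TRUE)) {
      stop("t-SNE embedding needs the 'Rtsne' package; install it or use ",
           "method = \"mds\"")
    }
    Y <- with_preserved_rng(seed, {
      Rtsne::Rtsne(stats::as.dist(D), is_distance = TRUE, dims = 2L,
                   perplexity = min(30, (n - 1) %/% 3), ...)$Y
    })
    return(unname(Y))
  }
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("UMAP embedding needs the 'uwot' package; install it or use ",
         "method = \"mds\"")
  }
  Y <- with_preserved_rng(seed, {
    uwot::umap(stats::as.dist(D), n_components = 2L,
               n_neighbors = min(15L, n - 1L), ...)
  })
  unname(Y)
}

#' Coupled-distance visualization coordinates for a fit
#'
#' Builds the coupled distance matrix from the stored data and a chosen
#' layer's projection, then embeds it.
#'
#' @param fit a `gule` fit with `keep_data = TRUE`.
#' @param lambda weight on the raw term.
#' @param layer which layer's projection to couple (default: last).
#' @param method,seed passed to [embed_coords()].
#' @return n x 2 coordinates.
#' @export
gule_visualize <- function(fit, lambda = 0.5, layer = length(fit$layers),
                           method = "mds", seed = fit$seed) {
  if (is.null(fit$X)) stop("fit was run with keep_data = FALSE")
  Draw <- compute_distance_matrix(fit$X, fit$metric)
  Dc <- coupled_distance(Draw, fit$layers[[layer]]$projection, lambda)
  embed_coords(Dc, method = method, seed = seed)
}
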