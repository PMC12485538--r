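#' Run one extraction-propagation layer
#'
#' A single layer of the two-layer network: pairwise distances of the input
#' points, class-consistent neighborhoods (fixed-size rule in layer 1,
#' adaptive gap rule in layer 2), the credibility graph, its average
#' connection strength `s` and cut exponent `beta = 1 - s`, and finally the
#' K-dimensional spectral projection of the degree-rescaled graph.
#'
#' @param points layer-1: the raw feature matrix; layer-2: the rows of the
#'   previous layer's projection.
#' @param layer 1 or 2. Layer 2 always measures proximity with the cosine
#'   distance.
#' @param K number of classes.
#' @param metric distance metric for layer 1.
#' @param k0 base neighborhood constant.
#' @param alpha credibility parameter; `NULL` selects the layer default
#'   ([alpha_for_layer()]).
#' @param cut `"acut"` (beta = 1 - s), `"ncut"` (beta = 1) or
#'   `"ratioassoc"` (beta = 0).
#' @param graph_type `"credibility"` or the `"selftuning"` Gaussian ablation
#'   graph.
#' @param kprime local-scale neighbor for the self-tuning ablation graph.
#' @param s_ncut weak-graph threshold for the adaptive cut: when the
#'   estimated strength `s` falls below it, the exact normalized-cut limit
#'   `beta = 1` is used instead of `beta = 1 - s`. In that regime the
#'   off-diagonal weights are a weak perturbation of the self-loops and the
#'   eigenvalue order under any `beta < 1` is decided by sampling
#'   fluctuations of local density rather than by class structure, whereas
#'   at the exact limit the top eigenspace provably spans the per-component
#'   indicator space. Set to 0 to disable snapping.
#' @return list with `projection` (`gule_projection`), `graph`
#'   (`gule_graph`), `neighborhoods`, `s`, `beta`, `kc`, `alpha`.
#' @export
run_layer <- function(points, layer, K, metric = "euclidean", k0 = 5L,
                      alpha = NULL, cut = "acut",
                      graph_type = "credibility", kprime = 7L,
                      s_ncut = 0.3) {
  points <- as.matrix(points)
  n <- nrow(points)
  wrap <- function(expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("layer ", layer, ": ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warning("layer ", layer, ": ", conditionMessage(w), call. = FALSE)
        invokeRestart("muffleWarning")
      })
  }
  wrap({
    D <- if (layer == 1L) compute_distance_matrix(points, metric)
         else cosine_distance_safe(points)
    kc <- neighborhood_size(n, K, k0)
    if (n < kc + 1L) stop("n (", n, ") below kc + 1 (", kc + 1L, ")")
    nb <- if (layer == 1L) estimate_neighborhoods_layer1(D, kc)
          else estimate_neighborhoods_layer2(D, kc, n, K)
    if (is.null(alpha)) alpha <- alpha_for_layer(n, K, layer)
    graph <- if (graph_type == "credibility") {
      build_credibility_graph(D, nb, alpha)
    } else {
      selftuning_graph(D, kprime)
    }
    s <- estimate_strength(graph, nb)
    beta <- switch(cut,
                   acut = if (s < s_ncut) 1 else beta_from_strength(s),
                   ncut = 1,
                   ratioassoc = 0,
                   stop("unknown cut '", cut, "'"))
    projection <- spectral_project(graph, K, beta)
    list(projection = projection, graph = graph, neighborhoods = nb,
         s = s, beta = beta, kc = kc, alpha = alpha)
  })
}

#' Two-layer credibility-graph clustering
#'
#' Fits the full pipeline: a first extraction-propagation layer on the raw
#' data (configurable metric, conservative credibility), a second layer on
#' the projected points (cosine distance, adaptive neighborhoods, alpha = 2),
#' and a completely-positive-factorization rotation of the final eigenbasis
#' whose row-wise absolute argmax gives the cluster labels.
#'
#' @param X numeric feature matrix, rows = samples.
#' @param K number of classes (>= 1).
#' @param metric layer-1 distance metric, or `"consensus"` to pick it by the
#'   mean pairwise-NMI consensus rule over `candidates`.
#' @param k0 base neighborhood constant (default 5).
#' @param alpha1,alpha2 credibility parameters; `alpha1 = NULL` uses the
#'   class-size rule (9 if `n/K <= 100`, else 6), `alpha2` defaults to 2.
#' @param layers 1 or 2 (default 2; 1 supports ablations).
#' @param seed integer fixing all stochastic components (rotation restarts).
#' @param cut `"acut"`, `"ncut"` or `"ratioassoc"` (ablation).
#' @param graph `"credibility"` or `"selftuning"` (ablation).
#' @param clusterer `"cpf"` (default), or `"kmeans"` / `"kmedoids"` baselines
#'   on the projected points (ablation).
#' @param candidates candidate metrics for `metric = "consensus"`.
#' @param s_ncut weak-graph threshold below which the adaptive cut takes the
#'   exact normalized-cut limit; see [run_layer()].
#' @param keep_data store `X` in the result (enables `plot()`).
#' @return an object of class `gule` with components `labels` (1..K),
#'   `layers` (per-layer summaries: `s`, `beta`, `kc`, `alpha`, eigenvalues,
#'   graph sparsity, the projection), `cpf`, `K`, `n`, `metric`, `seed`,
#'   `consensus` (when metric selection ran), and the matched `call`.
#' @seealso [run_layer()], [epm_solve()], [clustering_accuracy()]
#' @export
#' @examples
#' d <- make_blobs(n = 90, K = 3, separation = 20, spread = 1, seed = 1)
#' fit <- gule(d$X, K = 3)
#' table(fit$labels, d$truth)
gule <- function(X, K, metric = c("euclidean", "cosine", "correlation",
                                  "spearman", "consensus"),
                 k0 = 5L, alpha1 = NULL, alpha2 = 2, layers = 2L, seed = 0L,
                 cut = c("acut", "ncut", "ratioassoc"),
                 graph = c("credibility", "selftuning"),
                 clusterer = c("cpf", "kmeans", "kmedoids"),
                 candidates = c("euclidean", "cosine", "correlation",
                                "spearman"),
                 s_ncut = 0.3, keep_data = TRUE) {
  cl <- match.call()
  metric <- match.arg(metric)
  cut <- match.arg(cut)
  graph <- match.arg(graph)
  clusterer <- match.arg(clusterer)
  X <- as.matrix(X)
  n <- nrow(X)
  if (!layers %in% c(1L, 2L)) stop("layers must be 1 or 2")
  if (K < 1L) stop("K must be >= 1")
  kc0 <- neighborhood_size(n, K, k0)
  if (n < max(2 * K, kc0 + 2L)) {
    stop("too few samples (n = ", n, ") for K = ", K,
         " classes with kc = ", kc0)
  }

  consensus <- NULL
  if (metric == "consensus") {
    consensus <- consensus_select_metric(
      X, K, candidates = candidates, k0 = k0, alpha1 = alpha1,
      alpha2 = alpha2, layers = layers, seed = seed, cut = cut,
      graph = graph, clusterer = clusterer, s_ncut = s_ncut,
      keep_data = FALSE)
    metric <- consensus$metric
  }

  layer1 <- run_layer(X, 1L, K, metric = metric, k0 = k0, alpha = alpha1,
                      cut = cut, graph_type = graph, s_ncut = s_ncut)
  layer_fits <- list(layer1)
  if (layers == 2L) {
    layer_fits[[2L]] <- run_layer(layer1$projection$U, 2L, K, k0 = k0,
                                  alpha = alpha2, cut = cut,
                                  graph_type = "credibility",
                                  s_ncut = s_ncut)
  }
  U <- layer_fits[[length(layer_fits)]]$projection$U

  cpf <- NULL
  if (K == 1L) {
    labels <- rep.int(1L, n)
  } else if (clusterer == "cpf") {
    cpf <- epm_solve(U, seed = seed)
    labels <- cpf$labels
  } else if (clusterer == "kmeans") {
    labels <- with_preserved_rng(seed, stats::kmeans(U, K)$cluster)
  } else {
    labels <- cluster::pam(U, K, cluster.only = TRUE)
  }

  summaries <- lapply(layer_fits, function(lf) {
    nnz <- Matrix::nnzero(lf$graph$A) - nrow(lf$graph$A)
    list(s = lf$s, beta = lf$beta, kc = lf$kc, alpha = lf$alpha,
         eigvals = lf$projection$eigvals, gap = lf$projection$gap,
         nnz = nnz, projection = lf$projection,
         graph = lf$graph, neighborhoods = lf$neighborhoods)
  })

  structure(list(labels = as.integer(labels), K = K, n = n, metric = metric,
                 layers = summaries, cpf = cpf, seed = seed,
                 consensus = consensus,
                 config = list(k0 = k0, alpha1 = alpha1, alpha2 = alpha2,
                               layers = layers, cut = cut, graph = graph,
                               clusterer = clusterer),
                 X = if (keep_data) X else NULL,
                 call = cl),
            class = "gule")
}

#' @method print gule
#' @export
print.gule <- function(x, ...) {
  cat("Two-layer credibility-graph clustering\n")
  cat("  n = ", x$n, ", K = ", x$K, ", metric = ", x$metric, "\n", sep = "")
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  layer %d: kc = %d, alpha = %g, s = %.3f, beta = %.3f, gap = %.4g\n",
                l, ly$kc, ly$alpha, ly$s, ly$beta, ly$gap))
  }
  cat("  cluster sizes: ",
      paste(tabulate(x$labels, x$K), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @method summary gule
#' @export
summary.gule <- function(object, ...) {
  structure(list(fit = object), class = "summary.gule")
}

#' @method print summary.gule
#' @export
print.summary.gule <- function(x, ...) {
  f <- x$fit
  print(f)
  if (!is.null(f$cpf)) {
    cat(sprintf("  rotation objective: %.3g (%d restarts, %s)\n",
                f$cpf$objective, f$cpf$restarts_used,
                if (f$cpf$converged) "converged" else "not converged"))
  }
  last <- f$layers[[length(f$layers)]]
  cat("  leading eigenvalues (final layer): ",
      paste(format(round(last$eigvals, 4)), collapse = ", "), "\n", sep = "")
  if (!is.null(f$consensus)) {
    cat("  consensus scores: ",
        paste(names(f$consensus$scores),
              format(round(f$consensus$scores, 3)),
              sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Extract cluster labels from a fit
#'
#' @param object a `gule` fit.
#' @param ... ignored.
#' @return integer label vector in 1..K.
#' @export
labels.gule <- function(object, ...) object$labels

#' Plot a clustering fit
#'
#' For 2-D data, a scatter of the data colored by cluster; otherwise (or
#' with `which = "projection"`) the first two coordinates of the final-layer
#' spectral projection. `which = "spectrum"` plots the leading eigenvalues
#' per layer.
#'
#' @param x `gule` fit.
#' @param which `"data"`, `"projection"` or `"spectrum"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gule <- function(x, which = c("data", "projection", "spectrum"), ...) {
  which <- match.arg(which)
  pal <- grDevices::hcl.colors(max(3L, x$K), "Dark 3")
  if (which == "spectrum") {
    for (l in seq_along(x$layers)) {
      ev <- x$layers[[l]]$eigvals
      if (l == 1L) {
        graphics::plot(seq_along(ev), ev / ev[1], type = "b", pch = 19,
                       xlab = "index", ylab = "normalized eigenvalue",
                       ylim = c(0, 1), ...)
      } else {
        graphics::lines(seq_along(ev), ev / ev[1], type = "b", pch = 1)
      }
    }
    graphics::legend("bottomleft", legend = paste("layer",
                                                  seq_along(x$layers)),
                     pch = c(19, 1), bty = "n")
    return(invisible(x))
  }
  P <- if (which == "data" && !is.null(x$X) && ncol(x$X) == 2L) {
    x$X
  } else {
    x$layers[[length(x$layers)]]$projection$U[, 1:2, drop = FALSE]
  }
  graphics::plot(P[, 1], P[, 2], col = pal[x$labels], pch = 19,
                 xlab = "dim 1", ylab = "dim 2", ...)
  invisible(x)
}
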