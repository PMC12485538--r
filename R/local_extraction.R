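#' Base neighborhood size
#'
#' The conservative class-consistent neighborhood size
#' `kc = k0 + floor(log2(n / K))`, clamped to `n - 1` so a neighborhood (plus
#' its first excluded neighbor) never exceeds the dataset.
#'
#' @param n number of samples.
#' @param K number of classes.
#' @param k0 small base count guarding against over-small neighborhoods
#'   (default 5).
#' @return integer neighborhood size.
#' @export
#' @examples
#' neighborhood_size(1000, 10)  # 11
neighborhood_size <- function(n, K, k0 = 5L) {
  if (K < 1L) stop("K must be >= 1")
  if (n < K) stop("n (", n, ") must be at least K (", K, ")")
  if (k0 < 1L) stop("k0 must be >= 1")
  kc <- as.integer(k0 + floor(log2(n / K)))
  min(kc, n - 1L)
}

#' Credibility parameter alpha for a layer
#'
#' The confidence parameter of the credibility function. The first layer uses
#' a conservative alpha that depends on the average class size `n / K`
#' (9 when `n / K <= 100`, otherwise 6); the second layer, operating on
#' already-consolidated projected points, uses alpha = 2.
#'
#' @param n number of samples.
#' @param K number of classes.
#' @param layer 1 or 2.
#' @return numeric alpha.
#' @export
alpha_for_layer <- function(n, K, layer) {
  if (!layer %in% c(1L, 2L)) stop("layer must be 1 or 2")
  if (layer == 2L) return(2)
  if (n / K <= 100) 9 else 6
}

#' Enhanced credibility weight
#'
#' The sigmoid-lifted Gaussian credibility
#' `2 / (1 + exp((alpha * gamma)^2 / 2))` of a normalized distance
#' `gamma = d / omega_ij`. Equals `2 c / (1 + c)` with the plain credibility
#' `c = exp(-(alpha * gamma)^2 / 2)`; strictly decreasing in both `gamma`
#' and (for `gamma > 0`) `alpha`, with value 1 at `gamma = 0`. Overflow of
#' the exponential yields 0.
#'
#' @param gamma nonnegative normalized distance(s).
#' @param alpha positive confidence parameter.
#' @return weight(s) in (0, 1].
#' @export
#' @examples
#' enhanced_credibility(0, 2)     # 1
#' enhanced_credibility(1, 2)     # 2 / (1 + exp(2))
enhanced_credibility <- function(gamma, alpha) {
  if (any(gamma < 0)) stop("gamma must be >= 0")
  if (alpha <= 0) stop("alpha must be > 0")
  2 / (1 + exp((alpha * gamma)^2 / 2))
}

# Sorted neighbor order for point i: the point itself first, then the rest by
# ascending distance with ties broken by ascending index.
neighbor_order <- function(d, i) {
  ord <- order(d, seq_along(d))
  c(i, ord[ord != i])
}

#' First-layer class-consistent neighborhoods
#'
#' Every point's neighborhood is its `kc` nearest points (itself included,
#' first in the ordering; distance ties broken by ascending index). The
#' exclusion radius `omega_i` is the distance to the (kc+1)-st nearest point,
#' i.e. to the first neighbor deemed class-inconsistent.
#'
#' @param D distance matrix (`gule_dist` or plain symmetric matrix).
#' @param kc neighborhood size; `kc + 1` must not exceed n.
#' @return an object of class `gule_neighborhoods`: list with per-point
#'   `neighbors` (ordered index vectors), `omega`, `sizes`, `kc`, `layer`.
#' @export
estimate_neighborhoods_layer1 <- function(D, kc) {
  D <- as.matrix(D)
  n <- nrow(D)
  kc <- as.integer(kc)
  if (kc >= n) kc <- n - 1L  # cap: a point can have at most n-1 other points
  if (kc + 1L > n) stop("kc + 1 (", kc + 1L, ") exceeds n (", n, ")")
  neighbors <- vector("list", n)
  omega <- numeric(n)
  for (i in seq_len(n)) {
    ord <- neighbor_order(D[i, ], i)
    neighbors[[i]] <- ord[seq_len(kc)]
    omega[i] <- D[i, ord[kc + 1L]]
  }
  structure(list(neighbors = neighbors, omega = omega,
                 sizes = rep.int(kc, n), kc = kc, layer = 1L),
            class = "gule_neighborhoods")
}

#' Second-layer adaptive neighborhoods (gap rule)
#'
#' On projected points the class-consistent neighborhood is larger and its
#' size is chosen per point: with the neighbors of i sorted by ascending
#' distance (`i` itself first), `k_i` is the position `j >= kc` of the
#' largest forward distance gap `d(i, i_{j+1}) - d(i, i_j)` within a local
#' search window, capped at the average class size `floor(n / K)`. Gap ties
#' take the smallest `j`. `omega_i` is the distance to point `k_i + 1`.
#'
#' The window scans `j` in `[kc, min(n - 1, 2 * floor(n / K))]`; when `kc`
#' already exceeds the cap, `k_i` is clamped to `kc`.
#'
#' @param D cosine distance matrix of the projected points.
#' @param kc base neighborhood size.
#' @param n number of samples (must equal `nrow(D)`).
#' @param K number of classes.
#' @return `gule_neighborhoods` with `layer = 2`.
#' @export
estimate_neighborhoods_layer2 <- function(D, kc, n = nrow(D), K) {
  D <- as.matrix(D)
  if (n != nrow(D)) stop("n must equal nrow(D)")
  kc <- as.integer(kc)
  if (n <= kc) stop("n (", n, ") must exceed kc (", kc, ")")
  cap <- max(1L, n %/% K)
  W <- min(n - 1L, 2L * cap)
  neighbors <- vector("list", n)
  omega <- numeric(n)
  sizes <- integer(n)
  for (i in seq_len(n)) {
    ord <- neighbor_order(D[i, ], i)
    dsort <- D[i, ord]
    if (kc > cap || kc > W - 1L) {
      ki <- min(kc, n - 1L)  # clamp branch: no room to scan gaps
    } else {
      js <- kc:(W - 1L)
      gaps <- dsort[js + 1L] - dsort[js]
      jstar <- js[which.max(gaps)]  # first max = smallest j
      ki <- min(jstar, cap)
    }
    ki <- max(ki, min(kc, n - 1L))
    neighbors[[i]] <- ord[seq_len(ki)]
    sizes[i] <- ki
    omega[i] <- dsort[ki + 1L]
  }
  structure(list(neighbors = neighbors, omega = omega,
                 sizes = sizes, kc = kc, layer = 2L),
            class = "gule_neighborhoods")
}

#' @method print gule_neighborhoods
#' @export
print.gule_neighborhoods <- function(x, ...) {
  cat("Class-consistent neighborhoods (layer ", x$layer, ")\n", sep = "")
  cat("  points: ", length(x$neighbors),
      "   kc: ", x$kc,
      "   sizes: ", min(x$sizes), "-", max(x$sizes), "\n", sep = "")
  invisible(x)
}
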