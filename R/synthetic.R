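# Balanced class sizes: remainder goes to the earliest classes.
balanced_sizes <- function(n, K) {
  base <- n %/% K
  sizes <- rep.int(base, K)
  extra <- n - base * K
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

new_dataset <- function(X, truth, name, seed, params) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, truth = as.integer(truth), name = name,
                 seed = seed, params = params),
            class = "gule_dataset")
}

#' @method print gule_dataset
#' @export
print.gule_dataset <- function(x, ...) {
  cat("Synthetic dataset '", x$name, "': n = ", nrow(x$X),
      ", K = ", length(unique(x$truth)), ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Isotropic Gaussian blob control dataset
#'
#' `K` spherical Gaussian clusters with pairwise center separation at least
#' `separation` (centers on a regular circle in the first two coordinates)
#' and standard deviation `spread`; class sizes balanced with the remainder
#' assigned to the earliest classes.
#'
#' @param n samples.
#' @param K classes.
#' @param p dimensions (>= 2 unless K = 1).
#' @param separation minimum pairwise center distance (> 0).
#' @param spread per-coordinate standard deviation.
#' @param seed integer seed (bitwise-reproducible output).
#' @return `gule_dataset` with fields `X`, `truth`, `name`, `seed`, `params`.
#' @export
make_blobs <- function(n, K, p = 2L, separation = 20, spread = 1, seed = 0L) {
  if (n < K) stop("n must be at least K")
  if (separation <= 0) stop("separation must be > 0")
  if (p < 1L || (K > 1L && p < 2L)) stop("need p >= 2 for K > 1")
  sizes <- balanced_sizes(n, K)
  centers <- matrix(0, K, p)
  if (K > 1L) {
    R <- separation / (2 * sin(pi / K))  # adjacent centers exactly `separation` apart
    ang <- 2 * pi * (seq_len(K) - 1L) / K
    centers[, 1L] <- R * cos(ang)
    centers[, 2L] <- R * sin(ang)
  }
  X <- with_preserved_rng(seed, {
    do.call(rbind, lapply(seq_len(K), function(k) {
      sweep(matrix(stats::rnorm(sizes[k] * p, sd = spread), sizes[k], p),
            2L, centers[k, ], `+`)
    }))
  })
  new_dataset(X, rep.int(seq_len(K), sizes), "blobs", seed,
              list(n = n, K = K, p = p, separation = separation,
                   spread = spread))
}

#' Entangled benchmark: three interlocking curvilinear classes
#'
#' Three Archimedean spiral arms offset by 120 degrees in phase, each
#' sweeping 2.5 pi radians with radius growing from 1 to 5, plus isotropic
#' Gaussian jitter of standard deviation `noise`. The arms interlock (every
#' arm spans all directions and the full radius range), so the classes are
#' neither linearly nor radially separable, yet the inter-arm channel
#' (about 1.07 units wide before jitter) keeps them connectivity-separable
#' at the default noise.
#'
#' @param n samples (>= 60), balanced over the three arms.
#' @param noise jitter standard deviation (>= 0; default 0.1).
#' @param seed integer seed.
#' @return `gule_dataset`.
#' @export
make_entangled <- function(n, noise = 0.1, seed = 0L) {
  if (n < 60L) stop("n must be >= 60")
  if (noise < 0) stop("noise must be >= 0")
  sizes <- balanced_sizes(n, 3L)
  sweep_ang <- 2.5 * pi
  X <- with_preserved_rng(seed, {
    do.call(rbind, lapply(1:3, function(m) {
      t <- seq(0, 1, length.out = sizes[m])
      phi <- sweep_ang * t + 2 * pi * (m - 1L) / 3
      r <- 1 + 4 * t
      cbind(r * cos(phi), r * sin(phi)) +
        matrix(stats::rnorm(2L * sizes[m], sd = noise), ncol = 2L)
    }))
  })
  new_dataset(X, rep.int(1:3, sizes), "entangled", seed,
              list(n = n, noise = noise))
}

#' Compounded benchmark: classes of strongly differing densities
#'
#' Four classes with density contrast well above five-fold: a dense Gaussian
#' core (sd 0.25) at the origin, a sparse annulus (radii 4-6) enclosing it,
#' a compact Gaussian blob (sd 0.8) at (12, 0), and a sparse uniform bar
#' over \[-4, 4\] x \[9, 11\]. All nearest cross-class gaps are large
#' relative to each class's own neighbor spacing, so the classes are
#' connectivity-separable despite the nested geometry.
#'
#' @param n samples (>= 100), balanced over the four classes.
#' @param seed integer seed.
#' @return `gule_dataset`.
#' @export
make_compounded <- function(n, seed = 0L) {
  if (n < 100L) stop("n must be >= 100")
  sizes <- balanced_sizes(n, 4L)
  X <- with_preserved_rng(seed, {
    core <- matrix(stats::rnorm(2L * sizes[1L], sd = 0.25), ncol = 2L)
    r <- sqrt(stats::runif(sizes[2L], 4^2, 6^2))
    th <- stats::runif(sizes[2L], 0, 2 * pi)
    ring <- cbind(r * cos(th), r * sin(th))
    blob <- cbind(stats::rnorm(sizes[3L], 12, 0.8),
                  stats::rnorm(sizes[3L], 0, 0.8))
    bar <- cbind(stats::runif(sizes[4L], -4, 4),
                 stats::runif(sizes[4L], 9, 11))
    rbind(core, ring, blob, bar)
  })
  new_dataset(X, rep.int(1:4, sizes), "compounded", seed, list(n = n))
}

#' Rounded benchmark: two compact clusters wrapped by a curved cluster
#'
#' Two tight Gaussian clusters (sd 0.3) at (-2, 0) and (2, 0), partially
#' wrapped by a 240-degree circular arc of radius 6 with tangential jitter
#' (sd 0.15). The arc class is strongly non-convex: its centroid lies far
#' from every arc point.
#'
#' @param n samples (>= 100), balanced over the three classes.
#' @param seed integer seed.
#' @return `gule_dataset`.
#' @export
make_rounded <- function(n, seed = 0L) {
  if (n < 100L) stop("n must be >= 100")
  sizes <- balanced_sizes(n, 3L)
  X <- with_preserved_rng(seed, {
    c1 <- cbind(stats::rnorm(sizes[1L], -2, 0.3),
                stats::rnorm(sizes[1L], 0, 0.3))
    c2 <- cbind(stats::rnorm(sizes[2L], 2, 0.3),
                stats::rnorm(sizes[2L], 0, 0.3))
    th <- seq(-pi / 6, 7 * pi / 6, length.out = sizes[3L])
    arc <- cbind(6 * cos(th), 6 * sin(th)) +
      matrix(stats::rnorm(2L * sizes[3L], sd = 0.15), ncol = 2L)
    rbind(c1, c2, arc)
  })
  new_dataset(X, rep.int(1:3, sizes), "rounded", seed, list(n = n))
}
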