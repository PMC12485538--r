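#' Rotation objective for the nonnegative-basis problem
#'
#' The penalized rotation objective
#' `1/4 ||Q Q' - I||_F^2 + (K/n) ||(U Q)^-||_F^2`, where `(M)^-` is the
#' entrywise negative part `min(m_ij, 0)`. It vanishes exactly when `Q` is
#' orthogonal and `U Q` is entrywise nonnegative — i.e. when the rotated
#' eigenbasis matches an ideal nonnegative (Perron) basis.
#'
#' @param Q K x K rotation candidate.
#' @param U n x K orthonormal eigenbasis.
#' @return nonnegative scalar.
#' @export
epm_objective <- function(Q, U) {
  K <- ncol(U)
  n <- nrow(U)
  if (!is.matrix(Q) || nrow(Q) != K || ncol(Q) != K) {
    stop("Q must be ", K, " x ", K)
  }
  QQ <- tcrossprod(Q) - diag(K)
  neg <- pmin(U %*% Q, 0)
  0.25 * sum(QQ^2) + (K / n) * sum(neg^2)
}

# random orthogonal K x K matrix via QR of a Gaussian draw
random_orthogonal <- function(K) {
  qr.Q(qr(matrix(stats::rnorm(K * K), K, K)))
}

#' Solve for the rotation toward a nonnegative basis
#'
#' Minimizes [epm_objective()] by gradient descent on `Q` with gradient
#' `(Q Q' - I) Q + (2K/n) U' (U Q)^-`. Each iteration starts from step size
#' `step` and halves it until the objective does not increase, so the
#' objective trace is non-increasing by construction. Multiple restarts
#' (identity plus seeded random orthogonal starts) guard against the
#' nonconvexity; the restart with the lowest final objective is returned,
#' so the result is never worse than starting at the identity.
#'
#' @param U n x K orthonormal eigenbasis.
#' @param step initial step size (default 0.1).
#' @param max_iter iteration cap per restart (default 5000).
#' @param tol stop when the objective decrease falls below this (default
#'   1e-12).
#' @param n_restarts total restarts including the identity start (default 5).
#' @param seed optional integer seeding the random restarts; the caller's
#'   RNG state is restored on exit.
#' @return object of class `gule_cpf`: `Q`, `Utilde = U Q`, `labels`,
#'   `objective`, `trace` (of the winning restart), `restarts_used`,
#'   `converged`.
#' @export
epm_solve <- function(U, step = 0.1, max_iter = 5000L, tol = 1e-12,
                      n_restarts = 5L, seed = NULL) {
  U <- as.matrix(U)
  K <- ncol(U)
  n <- nrow(U)

  if (K == 1L) {
    # scalar case: Q = +/-1 orients the Perron vector nonnegative
    q <- if (sum(U) < 0) -1 else 1
    Q <- matrix(q, 1L, 1L)
    Ut <- U * q
    return(structure(list(Q = Q, Utilde = Ut, labels = cpf_labels(Ut),
                          objective = epm_objective(Q, U),
                          trace = epm_objective(Q, U),
                          restarts_used = 1L, converged = TRUE),
                     class = "gule_cpf"))
  }

  starts <- vector("list", n_restarts)
  starts[[1L]] <- diag(K)
  if (n_restarts > 1L) {
    starts[2:n_restarts] <- with_preserved_rng(seed, {
      lapply(seq_len(n_restarts - 1L), function(r) random_orthogonal(K))
    })
  }

  descend <- function(Q0) {
    obj <- epm_objective(Q0, U)
    trace <- obj
    Q <- Q0
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      UQ <- U %*% Q
      grad <- (tcrossprod(Q) - diag(K)) %*% Q +
        (2 * K / n) * crossprod(U, pmin(UQ, 0))
      h <- step
      repeat {
        Qn <- Q - h * grad
        objn <- epm_objective(Qn, U)
        if (objn <= obj || h < 1e-14) break
        h <- h / 2
      }
      if (objn > obj) break  # no descent direction left
      delta <- obj - objn
      Q <- Qn
      obj <- objn
      trace <- c(trace, obj)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    list(Q = Q, objective = obj, trace = trace, converged = converged)
  }

  runs <- lapply(starts, descend)
  best <- runs[[which.min(vapply(runs, `[[`, 0, "objective"))]]
  if (!any(vapply(runs, `[[`, FALSE, "converged"))) {
    warning("rotation solver did not converge in any restart; ",
            "returning best iterate")
  }
  Ut <- U %*% best$Q
  structure(list(Q = best$Q, Utilde = Ut, labels = cpf_labels(Ut),
                 objective = best$objective, trace = best$trace,
                 restarts_used = n_restarts, converged = best$converged),
            class = "gule_cpf")
}

#' Labels from a rotated eigenbasis
#'
#' Each point is assigned to the class of its largest-magnitude coordinate
#' in the rotated basis: `label(i) = argmax_k |u~_ik|`, ties broken by the
#' smallest class index. An all-zero row is degenerate and labeled class 1
#' with a warning.
#'
#' @param Utilde n x K rotated basis.
#' @return integer label vector in 1..K.
#' @export
cpf_labels <- function(Utilde) {
  Utilde <- as.matrix(Utilde)
  a <- abs(Utilde)
  if (any(rowSums(a) == 0)) {
    warning(sum(rowSums(a) == 0),
            " all-zero row(s) in the rotated basis; labeled class 1")
  }
  apply(a, 1L, which.max)  # first max = smallest class index
}

#' @method print gule_cpf
#' @export
print.gule_cpf <- function(x, ...) {
  cat("CPF rotation: K = ", ncol(x$Q),
      ", objective = ", format(signif(x$objective, 4)),
      ", ", length(x$trace) - 1L, " iterations",
      if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}
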