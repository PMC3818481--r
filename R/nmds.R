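#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Finds a k-dimensional configuration whose inter-point distances match
#' the rank order of the input dissimilarities, minimizing Kruskal's
#' stress-1
#' \deqn{\sigma_1 = \sqrt{\sum_{i<j} (\hat d_{ij} - d_{ij})^2 / \sum_{i<j} d_{ij}^2}}
#' where d are configuration distances and \eqn{\hat d} their monotone
#' (pool-adjacent-violators) regression on the dissimilarity order. Ties
#' in the dissimilarities follow Kruskal's primary approach (tied values
#' may take unequal fitted values). Optimization alternates the isotonic
#' fit with a Guttman majorization step; a step-halving safeguard makes
#' the recorded stress sequence non-increasing. The first restart starts
#' from classical (metric) scaling, the remaining restarts from random
#' configurations; the lowest-stress solution is returned.
#'
#' @param d A `dist` object (n >= k + 1 units).
#' @param k Embedding dimension (default 2).
#' @param n_restarts Number of starts (default 8; first is metric).
#' @param max_iter Iterations per restart (default 300).
#' @param tol Relative stress-change convergence tolerance (default 1e-8).
#' @param seed Integer seed for the random starts.
#' @return Object of class `nmds_fit`: `points` (n x k, labelled),
#'   `stress`, `stress_trace` (best restart), `converged`, `all_stress`,
#'   `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2L, n_restarts = 8L, max_iter = 300L,
                 tol = 1e-8, seed = NULL) {
  stopifnot(inherits(d, "dist"), k >= 1, n_restarts >= 1, max_iter >= 1)
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 points")
  labs <- attr(d, "Labels") %||% as.character(seq_len(n))
  delta <- as.vector(d)
  ord <- order(delta)

  stress_of <- function(dc) {
    dhat <- numeric(length(dc))
    dhat[ord] <- stats::isoreg(dc[ord])$yf
    list(stress = sqrt(sum((dhat - dc)^2) / sum(dc^2)), dhat = dhat)
  }

  run_restart <- function(X) {
    dc <- as.vector(stats::dist(X))
    if (all(dc == 0)) dc <- dc + 1e-8
    cur <- stress_of(dc)
    trace <- cur$stress
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      # Guttman transform with current disparities
      ratio <- ifelse(dc > 0, cur$dhat / dc, 0)
      B <- matrix(0, n, n)
      B[lower.tri(B)] <- -ratio
      B <- B + t(B)
      diag(B) <- -rowSums(B)
      Xn <- B %*% X / n
      dcn <- as.vector(stats::dist(Xn))
      nxt <- stress_of(dcn)
      # safeguard: halve the step until stress does not increase
      half <- 0L
      while (nxt$stress > cur$stress + 1e-15 && half < 20L) {
        Xn <- (Xn + X) / 2
        dcn <- as.vector(stats::dist(Xn))
        nxt <- stress_of(dcn)
        half <- half + 1L
      }
      if (nxt$stress > cur$stress) { converged <- TRUE; break }
      improve <- cur$stress - nxt$stress
      X <- Xn; dc <- dcn; cur <- nxt
      trace <- c(trace, cur$stress)
      if (improve <= tol * max(cur$stress, 1e-12)) { converged <- TRUE; break }
    }
    list(X = X, stress = cur$stress, trace = trace, converged = converged)
  }

  fits <- with_seed(seed, {
    lapply(seq_len(n_restarts), function(s) {
      X <- if (s == 1L) {
        X0 <- suppressWarnings(stats::cmdscale(d, k = k))
        if (ncol(X0) < k)
          X0 <- cbind(X0, matrix(stats::rnorm(n * (k - ncol(X0)), sd = 1e-4),
                                 n))
        X0
      } else {
        matrix(stats::rnorm(n * k), n, k) * stats::sd(delta)
      }
      run_restart(X)
    })
  })
  stresses <- vapply(fits, `[[`, numeric(1), "stress")
  best <- fits[[which.min(stresses)]]
  pts <- best$X
  dimnames(pts) <- list(labs, paste0("NMDS", seq_len(k)))
  structure(list(points = pts, stress = best$stress,
                 stress_trace = best$trace, converged = best$converged,
                 all_stress = stresses, n_restarts = as.integer(n_restarts),
                 seed = seed),
            class = "nmds_fit")
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS: %d points in %d dimensions, stress-1 = %.4f (%s, %d restarts)\n",
              nrow(x$points), ncol(x$points), x$stress,
              if (x$converged) "converged" else "not converged",
              x$n_restarts))
  invisible(x)
}

#' @export
plot.nmds_fit <- function(x, ...) {
  graphics::plot(x$points[, 1], x$points[, 2],
                 xlab = colnames(x$points)[1], ylab = colnames(x$points)[2],
                 main = sprintf("NMDS (stress: %.4f)", x$stress), ...)
  graphics::text(x$points[, 1], x$points[, 2], rownames(x$points),
                 pos = 3, cex = 0.7)
  invisible(x)
}
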