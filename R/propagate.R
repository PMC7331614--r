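#' Label propagation over the normalized network
#'
#' The core smoothing step: given seed labels y on the nodes of the
#' symmetrically normalized network W', iterate
#' \deqn{f^{(r)} = \lambda W' f^{(r-1)} + (1 - \lambda) y}
#' until the largest per-node change falls below `tol`. Because the
#' spectral radius of W' is at most 1 and 0 < lambda < 1, the iteration
#' contracts to the unique fixed point
#' \deqn{f = (1 - \lambda)(I - \lambda W')^{-1} y,}
#' which [propagate_exact()] computes directly by a dense solve (the test
#' oracle). The propagated score of a gene summarizes how metabolically
#' enriched its network neighborhood is, so genes whose own metabolites
#' are unmeasured can still accumulate signal from enriched neighbors.
#'
#' @name propagate
#' @keywords internal
NULL

new_mp_propagation <- function(scores, iterations, converged, lambda, tol,
                               method) {
  structure(list(scores = scores, iterations = iterations,
                 converged = converged, lambda = lambda, tol = tol,
                 method = method), class = "mp_propagation")
}

#' @export
print.mp_propagation <- function(x, ...) {
  cat(sprintf("<mp_propagation> %d genes, lambda = %g, %s (%s iterations)\n",
              length(x$scores), x$lambda, x$method,
              if (is.na(x$iterations)) "no" else x$iterations))
  invisible(x)
}

map_seeds_to_nodes <- function(nnet, seeds) {
  nodes <- nnet$nodes
  y <- stats::setNames(numeric(length(nodes)), nodes)
  if (is.data.frame(seeds)) seeds <- seed_vector(seeds)
  stopifnot(is.numeric(seeds), !is.null(names(seeds)))
  known <- intersect(names(seeds), nodes)
  missing <- setdiff(names(seeds), nodes)
  if (length(missing)) {
    warning(length(missing), " seed gene(s) absent from the network ignored")
  }
  y[known] <- seeds[known]
  y
}

#' Iterative label propagation
#'
#' @param nnet A `mp_network_norm` from [normalize_network()].
#' @param seeds Seed labels: named numeric vector or a data frame from
#'   [me_score()]. Seed genes absent from the network are ignored with a
#'   warning; network genes without a seed start at 0.
#' @param lambda Propagation weight in (0, 1); default 0.99, placing
#'   almost all weight on the network term.
#' @param tol Convergence tolerance on the L-infinity score change
#'   (default 1e-6).
#' @param max_iter Iteration cap (default 10000). Non-convergence raises a
#'   condition of class `mp_convergence_error` carrying the last iterate
#'   and residual.
#' @return A `mp_propagation`: named `scores`, `iterations`, `converged`.
#' @export
propagate_labels <- function(nnet, seeds, lambda = 0.99, tol = 1e-6,
                             max_iter = 10000) {
  stopifnot(inherits(nnet, "mp_network_norm"),
            lambda > 0, lambda < 1, tol > 0, max_iter >= 1)
  y <- map_seeds_to_nodes(nnet, seeds)
  W <- nnet$W
  f <- unname(y)
  base <- (1 - lambda) * unname(y)
  for (r in seq_len(max_iter)) {
    f_new <- lambda * as.numeric(W %*% f) + base
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta <= tol) {
      return(new_mp_propagation(stats::setNames(f, nnet$nodes), r, TRUE,
                                lambda, tol, "iterative"))
    }
  }
  cond <- structure(
    class = c("mp_convergence_error", "error", "condition"),
    list(message = sprintf(
      "propagation did not converge in %d iterations (residual %.3g > tol %.3g)",
      max_iter, delta, tol),
      call = sys.call(-1),
      last = stats::setNames(f, nnet$nodes), residual = delta))
  stop(cond)
}

#' Closed-form label propagation (dense solve)
#'
#' Computes the fixed point f = (1 - lambda) (I - lambda W')^{-1} y
#' directly. Intended as the exact reference for small networks; guarded
#' to at most `max_nodes` nodes because the solve is dense.
#'
#' @inheritParams propagate_labels
#' @param max_nodes Dense-solve guard (default 2000).
#' @return A `mp_propagation` with `method = "exact"`.
#' @export
propagate_exact <- function(nnet, seeds, lambda = 0.99, max_nodes = 2000) {
  stopifnot(inherits(nnet, "mp_network_norm"), lambda > 0, lambda < 1)
  n <- length(nnet$nodes)
  if (n > max_nodes) {
    stop("network too large for the dense closed-form solve (", n, " > ",
         max_nodes, " nodes)")
  }
  y <- map_seeds_to_nodes(nnet, seeds)
  A <- diag(n) - lambda * as.matrix(nnet$W)
  f <- solve(A, (1 - lambda) * unname(y))
  new_mp_propagation(stats::setNames(as.numeric(f), nnet$nodes), NA_integer_,
                     TRUE, lambda, NA_real_, "exact")
}
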