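#' Graph Laplacian of a positive-link matrix
#'
#' @param positive Symmetric binary matrix with zero diagonal.
#' @return List with `L = D - positive` and the degree matrix `D`
#'   (diagonal of row sums).
#' @export
graph_laplacian <- function(positive) {
  d <- rowSums(positive)
  list(L = diag(d, nrow(positive)) - positive, D = diag(d, nrow(positive)))
}

#' Regularized symmetric-NMF objective
#'
#' \deqn{f(H) = \|A - H H^T\|_F^2 + \gamma_1 \,\mathrm{tr}(H^T A^n H)
#'   + \gamma_2 \,\mathrm{tr}(H^T L H)}
#' where \eqn{L} is the Laplacian of the positive-link matrix \eqn{A^p}.
#' The first term fits the topology; the second pushes cannot-linked
#' nodes into different communities; the third pulls must-linked nodes
#' into the same community.
#'
#' @param signed An `sscd_signed` (see [encode_signed()]).
#' @param H Nonnegative `n x k` matrix.
#' @param gamma1,gamma2 Nonnegative regularization weights.
#' @return The objective value (scalar).
#' @export
sscd_objective <- function(signed, H, gamma1 = 1, gamma2 = 1) {
  A <- signed$network$adjacency
  if (nrow(H) != nrow(A)) rlang::abort("H and adjacency have incompatible shapes")
  R <- A - H %*% t(H)
  lap <- graph_laplacian(signed$positive)
  sum(R * R) +
    gamma1 * sum(H * (signed$negative %*% H)) +
    gamma2 * sum(H * (lap$L %*% H))
}

#' One multiplicative update of the factor matrix
#'
#' Elementwise rule derived from the KKT fixed-point condition of the
#' regularized objective:
#' \deqn{H_{ij} \leftarrow H_{ij}\,
#'   \frac{(2 A H + \gamma_2 A^p H)_{ij}}
#'        {(2 H H^T H + \gamma_1 A^n H + \gamma_2 D H)_{ij}}}
#' Denominator entries are floored at `eps` to guard 0/0; nonzero
#' denominators are untouched, so an exact fixed point stays fixed.
#'
#' @param H Current nonnegative `n x k` matrix.
#' @param signed An `sscd_signed`.
#' @param D Degree matrix of the positive links (from [graph_laplacian()]);
#'   computed if `NULL`.
#' @inheritParams sscd_objective
#' @param eps Denominator floor.
#' @return Updated matrix `H'`, same shape, nonnegative.
#' @export
sscd_update <- function(H, signed, D = NULL, gamma1 = 1, gamma2 = 1, eps = 1e-10) {
  A <- signed$network$adjacency
  if (is.null(D)) D <- graph_laplacian(signed$positive)$D
  num <- 2 * (A %*% H) + gamma2 * (signed$positive %*% H)
  den <- 2 * H %*% crossprod(H) + gamma1 * (signed$negative %*% H) + gamma2 * (D %*% H)
  Hn <- H * num / pmax(den, eps)
  if (any(!is.finite(Hn))) {
    bad <- which(!is.finite(Hn), arr.ind = TRUE)
    rlang::abort(sprintf("non-finite factor entries after update (first at row %d, col %d)",
                         bad[1, 1], bad[1, 2]))
  }
  Hn
}

# shared multiplicative-update engine: minimizes
#   ||A - HH'||_F^2 + tr(H' (Rpos - Rneg) H)
# with Rpos, Rneg entrywise-nonnegative symmetric matrices. Update:
#   H <- H * (2AH + Rneg H) / (2HH'H + Rpos H)
# (matches sscd_update with Rpos = g1*An + g2*D, Rneg = g2*Ap).
mu_engine <- function(A, Rpos, Rneg, k, max_iter = 200, tol = 1e-6,
                      seed = NULL, eps = 1e-10, n_restarts = 1) {
  n <- nrow(A)
  if (k > n) rlang::abort(sprintf("k = %d exceeds number of nodes n = %d", k, n))
  if (k < 1) rlang::abort("k must be >= 1")
  obj <- function(H) {
    R <- A - H %*% t(H)
    sum(R * R) + sum(H * ((Rpos - Rneg) %*% H))
  }
  run_one <- function(s) {
    init <- function() matrix(stats::runif(n * k, 0.01, 1), n, k)
    H <- if (is.null(s)) init() else withr::with_seed(s, init())
    trace <- obj(H)
    converged <- FALSE
    it <- 0L
    for (it in seq_len(max_iter)) {
      num <- 2 * (A %*% H) + Rneg %*% H
      den <- 2 * H %*% crossprod(H) + Rpos %*% H
      H <- H * num / pmax(den, eps)
      if (any(!is.finite(H))) rlang::abort("non-finite factor entries during fit")
      f <- obj(H)
      if (!is.finite(f)) rlang::abort("non-finite objective during fit")
      trace <- c(trace, f)
      prev <- trace[it]
      if (abs(f - prev) / max(prev, 1e-12) < tol) {
        converged <- TRUE
        break
      }
    }
    list(H = H, objective_trace = trace, n_iter = it, converged = converged)
  }
  if (n_restarts <= 1) {
    res <- run_one(seed)
  } else {
    seeds <- if (is.null(seed)) rep(list(NULL), n_restarts) else
      as.list(derive_seed(seed, "restart", seq_len(n_restarts)))
    runs <- lapply(seeds, run_one)
    res <- runs[[which.min(vapply(runs, function(r) min(r$objective_trace), 0))]]
  }
  res
}

new_fit <- function(engine_res, nodes, method, params, seed) {
  structure(list(H = engine_res$H,
                 nodes = nodes,
                 objective_trace = engine_res$objective_trace,
                 n_iter = engine_res$n_iter,
                 converged = engine_res$converged,
                 method = method, params = params, seed = seed),
            class = "sscd_fit")
}

#' Fit the semi-supervised community model
#'
#' Minimizes the objective of [sscd_objective()] over nonnegative
#' `n x k` matrices `H` by the multiplicative update of [sscd_update()],
#' starting from a seeded uniform-(0.01, 1) initialization, until the
#' relative objective change drops below `tol` or `max_iter` is reached.
#' With `gamma1 = gamma2 = 0` (or no constraints) this is plain
#' symmetric NMF.
#'
#' @param x An `sscd_signed`, or an `sscd_network` (combined with
#'   `constraints`).
#' @param k Number of communities.
#' @param constraints Optional constraint tibble when `x` is a network.
#' @inheritParams sscd_objective
#' @param max_iter Maximum number of update iterations.
#' @param tol Relative objective-change convergence threshold.
#' @param seed Integer seed for the initialization (`NULL`: current RNG).
#' @param eps Denominator floor of the update.
#' @param n_restarts Number of seeded restarts; the best-objective run is
#'   kept. Default 1.
#' @return An `sscd_fit`: the factor matrix `H`, objective trace,
#'   iteration count, convergence flag, and fit metadata. Use
#'   [hard_assign()] / [generics::tidy()] for memberships.
#' @examples
#' sim <- planted_partition(c(20, 20), p_in = 0.5, p_out = 0.02, seed = 1)
#' fit <- sscd_fit(sim$network, k = 2, seed = 1)
#' nmi(hard_assign(fit), sim$truth)
#' @export
sscd_fit <- function(x, k, constraints = NULL, gamma1 = 1, gamma2 = 1,
                     max_iter = 200, tol = 1e-6, seed = NULL, eps = 1e-10,
                     n_restarts = 1) {
  signed <- if (inherits(x, "sscd_signed")) x else encode_signed(x, constraints)
  stopifnot(gamma1 >= 0, gamma2 >= 0, tol > 0, eps > 0)
  A <- signed$network$adjacency
  lap <- graph_laplacian(signed$positive)
  res <- mu_engine(A,
                   Rpos = gamma1 * signed$negative + gamma2 * lap$D,
                   Rneg = gamma2 * signed$positive,
                   k = k, max_iter = max_iter, tol = tol, seed = seed,
                   eps = eps, n_restarts = n_restarts)
  new_fit(res, signed$network$nodes, "sscd",
          list(k = k, gamma1 = gamma1, gamma2 = gamma2,
               max_iter = max_iter, tol = tol, eps = eps), seed)
}

#' Harden a factor matrix into a partition
#'
#' Node `i` goes to `argmax_j H[i, j]`; ties break to the lowest column
#' index. All-zero rows go to community 1 with a warning. Community
#' indices are compacted (renumbered by first appearance) so empty
#' communities disappear from the report.
#'
#' @param model An `sscd_fit`, or a bare nonnegative matrix with node
#'   identifiers as rownames.
#' @return A partition tibble (`node`, `community`).
#' @export
hard_assign <- function(model) {
  if (inherits(model, "sscd_fit")) {
    H <- model$H
    nodes <- model$nodes
  } else {
    H <- model
    nodes <- rownames(H) %||% as.character(seq_len(nrow(H)))
  }
  if (ncol(H) < 1) rlang::abort("factor matrix needs at least one column")
  zero <- rowSums(H) == 0
  if (any(zero)) {
    rlang::warn(sprintf("%d all-zero row(s) in H assigned to community 1", sum(zero)))
  }
  as_partition(tibble::tibble(node = nodes, community = max.col(H, ties.method = "first")))
}

#' @export
print.sscd_fit <- function(x, ...) {
  cat(sprintf("<sscd_fit> method=%s, n=%d, k=%d, %d iterations (%s), objective %.6g\n",
              x$method, nrow(x$H), ncol(x$H), x$n_iter,
              if (x$converged) "converged" else "max_iter reached",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}
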