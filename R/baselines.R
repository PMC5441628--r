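#' Comparison methods: constrained symmetric NMF baselines
#'
#' Three published semi-supervised factorization schemes, each reduced to
#' the single-network symmetric form used for method comparison:
#'
#' * `fit_nmf_lse()` — adds a Laplacian penalty
#'   \eqn{\lambda\,\mathrm{tr}(H^T L_m H)} built from the must-link graph
#'   only; cannot-link constraints have no effect.
#' * `fit_pmf()` — adds \eqn{\mathrm{tr}(H^T \Theta H)} with
#'   \eqn{\Theta_{ij} = \delta} at cannot-link pairs, \eqn{-\theta} at
#'   must-link pairs, 0 otherwise; the positive part of \eqn{\Theta} goes
#'   to the update's denominator, the negative part to its numerator.
#' * `fit_snmf_ss()` — factorizes the modified adjacency
#'   \eqn{\tilde A = A - \alpha M + \beta C} (`M`, `C` binary constraint
#'   matrices), negative entries clamped at 0 before the plain symmetric
#'   NMF. As printed, this formula penalizes must-links and rewards
#'   cannot-links; `flip_signs = TRUE` swaps the roles.
#'
#' With no constraints all three reduce to plain symmetric NMF and, on
#' identical seeds, match [sscd_fit()] at `gamma1 = gamma2 = 0`
#' iteration for iteration.
#'
#' @param network An `sscd_network`.
#' @param k Number of communities.
#' @param constraints A constraint tibble (may be `NULL` / empty).
#' @param lse_weight Laplacian weight \eqn{\lambda} (default 1).
#' @param delta,theta Cannot-link / must-link penalties of the
#'   \eqn{\Theta} scheme (defaults 2 and 1).
#' @param alpha,beta Must-link / cannot-link weights of the modified
#'   adjacency (defaults 0.001 and 0.1).
#' @param flip_signs Swap the roles of `alpha` and `beta` (see above).
#' @inheritParams sscd_fit
#' @return An `sscd_fit`.
#' @name baselines
NULL

#' @rdname baselines
#' @export
fit_nmf_lse <- function(network, k, constraints = NULL, lse_weight = 1,
                        max_iter = 200, tol = 1e-6, seed = NULL, eps = 1e-10,
                        n_restarts = 1) {
  signed <- encode_signed(network, constraints)
  lap <- graph_laplacian(signed$positive)
  res <- mu_engine(network$adjacency,
                   Rpos = lse_weight * lap$D,
                   Rneg = lse_weight * signed$positive,
                   k = k, max_iter = max_iter, tol = tol, seed = seed,
                   eps = eps, n_restarts = n_restarts)
  new_fit(res, network$nodes, "nmf_lse",
          list(k = k, lse_weight = lse_weight, max_iter = max_iter,
               tol = tol, eps = eps), seed)
}

#' @rdname baselines
#' @export
fit_pmf <- function(network, k, constraints = NULL, delta = 2, theta = 1,
                    max_iter = 200, tol = 1e-6, seed = NULL, eps = 1e-10,
                    n_restarts = 1) {
  signed <- encode_signed(network, constraints)
  res <- mu_engine(network$adjacency,
                   Rpos = delta * signed$negative,
                   Rneg = theta * signed$positive,
                   k = k, max_iter = max_iter, tol = tol, seed = seed,
                   eps = eps, n_restarts = n_restarts)
  new_fit(res, network$nodes, "pmf",
          list(k = k, delta = delta, theta = theta, max_iter = max_iter,
               tol = tol, eps = eps), seed)
}

#' @rdname baselines
#' @export
fit_snmf_ss <- function(network, k, constraints = NULL, alpha = 0.001,
                        beta = 0.1, flip_signs = FALSE, max_iter = 200,
                        tol = 1e-6, seed = NULL, eps = 1e-10, n_restarts = 1) {
  At <- snmf_adjacency(network, constraints, alpha = alpha, beta = beta,
                       flip_signs = flip_signs)
  zero <- matrix(0, nrow(At), ncol(At))
  res <- mu_engine(At, Rpos = zero, Rneg = zero, k = k, max_iter = max_iter,
                   tol = tol, seed = seed, eps = eps, n_restarts = n_restarts)
  new_fit(res, network$nodes, "snmf_ss",
          list(k = k, alpha = alpha, beta = beta, flip_signs = flip_signs,
               max_iter = max_iter, tol = tol, eps = eps), seed)
}

#' Constraint-modified adjacency of the SNMF_SS scheme
#'
#' \eqn{\tilde A = A - \alpha M + \beta C} with `M` / `C` the binary
#' must-link / cannot-link matrices; entries driven negative are clamped
#' at 0 (the multiplicative update cannot accept them) with a message.
#'
#' @inheritParams baselines
#' @return The modified adjacency matrix.
#' @export
snmf_adjacency <- function(network, constraints = NULL, alpha = 0.001,
                           beta = 0.1, flip_signs = FALSE) {
  signed <- encode_signed(network, constraints)
  M <- signed$positive
  C <- signed$negative
  At <- if (flip_signs) network$adjacency + alpha * M - beta * C
        else network$adjacency - alpha * M + beta * C
  n_clamped <- sum(At < 0)
  if (n_clamped > 0) {
    rlang::inform(sprintf("modified adjacency had %d negative entries clamped at 0", n_clamped))
    At[At < 0] <- 0
  }
  At
}

#' Dispatch a detection method by name
#'
#' @param method One of `"sscd"`, `"nmf_lse"`, `"pmf"`, `"snmf_ss"`.
#' @param network An `sscd_network`.
#' @param k Number of communities.
#' @param constraints Constraint tibble or `NULL`.
#' @param ... Passed to the chosen fitter (weights, `seed`, `max_iter`, ...).
#' @return An `sscd_fit`.
#' @export
fit_method <- function(method, network, k, constraints = NULL, ...) {
  method <- match.arg(method, c("sscd", "nmf_lse", "pmf", "snmf_ss"))
  switch(method,
         sscd = sscd_fit(network, k = k, constraints = constraints, ...),
         nmf_lse = fit_nmf_lse(network, k = k, constraints = constraints, ...),
         pmf = fit_pmf(network, k = k, constraints = constraints, ...),
         snmf_ss = fit_snmf_ss(network, k = k, constraints = constraints, ...))
}
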