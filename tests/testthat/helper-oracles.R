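# Independent, scalar-loop reference implementations. These stay
# deliberately naive (double loops, no matrix algebra) so they cannot
# share a defect with the package's vectorized code paths.

# partition tibble from a bare community vector
part <- function(v, nodes = paste0("n", seq_along(v))) {
  as_partition(stats::setNames(v, nodes))
}

oracle_confusion <- function(cvec, gvec) {
  cs <- unique(cvec)
  gs <- unique(gvec)
  Fm <- matrix(0L, length(cs), length(gs))
  for (i in seq_along(cvec)) {
    r <- match(cvec[i], cs)
    cl <- match(gvec[i], gs)
    Fm[r, cl] <- Fm[r, cl] + 1L
  }
  Fm
}

oracle_nmi <- function(cvec, gvec, base = exp(1)) {
  Fm <- oracle_confusion(cvec, gvec)
  n <- length(cvec)
  num <- 0
  for (i in seq_len(nrow(Fm))) {
    for (j in seq_len(ncol(Fm))) {
      if (Fm[i, j] > 0) {
        num <- num + Fm[i, j] * log(Fm[i, j] * n / (sum(Fm[i, ]) * sum(Fm[, j])), base = base)
      }
    }
  }
  den <- 0
  for (i in seq_len(nrow(Fm))) den <- den + sum(Fm[i, ]) * log(sum(Fm[i, ]) / n, base = base)
  for (j in seq_len(ncol(Fm))) den <- den + sum(Fm[, j]) * log(sum(Fm[, j]) / n, base = base)
  if (den == 0) return(if (nrow(Fm) == 1 && ncol(Fm) == 1) 1 else 0)
  -2 * num / den
}

oracle_purity <- function(cvec, gvec) {
  Fm <- oracle_confusion(cvec, gvec)
  s <- 0
  for (i in seq_len(nrow(Fm))) s <- s + max(Fm[i, ])
  s / length(cvec)
}

# term-by-term objective: ||A - HH'||_F^2 + g1 tr(H'An H) + g2 tr(H'L H)
oracle_objective <- function(A, Ap, An, H, g1, g2) {
  n <- nrow(A)
  k <- ncol(H)
  f <- 0
  for (i in 1:n) {
    for (j in 1:n) {
      hh <- 0
      for (cc in 1:k) hh <- hh + H[i, cc] * H[j, cc]
      f <- f + (A[i, j] - hh)^2
      f <- f + g1 * An[i, j] * hh
      f <- f - g2 * Ap[i, j] * hh
    }
    f <- f + g2 * sum(Ap[i, ]) * sum(H[i, ]^2)
  }
  f
}

# undamped multiplicative step of plain symmetric NMF, coded independently
plain_symnmf_step <- function(H, A, eps = 1e-10) {
  num <- 2 * (A %*% H)
  den <- 2 * H %*% (t(H) %*% H)
  H * num / pmax(den, eps)
}

# Erdos-Renyi style random network + random ground-truth labels
rand_instance <- function(n, p = 0.3, kt = 2, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(stats::rbinom(n * n, 1, p), n, n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    g <- sample(seq_len(kt), n, replace = TRUE)
    g[seq_len(kt)] <- seq_len(kt)  # every community nonempty
    list(network = sscd:::new_network(paste0("n", 1:n), A),
         truth = part(g))
  })
}

random_partition <- function(n, kmax = 4, seed = NULL) {
  draw <- function() {
    k <- sample(seq_len(min(kmax, n)), 1)
    g <- sample(seq_len(k), n, replace = TRUE)
    g[seq_len(k)] <- seq_len(k)
    g
  }
  if (is.null(seed)) part(draw()) else part(withr::with_seed(seed, draw()))
}
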