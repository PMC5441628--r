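test_that("the Laplacian is degree-minus-adjacency with zero row sums and PSD", {
  z <- matrix(0, 3, 3)
  expect_equal(graph_laplacian(z)$L, z)
  expect_equal(graph_laplacian(z)$D, z)

  Ap <- matrix(0, 3, 3)
  Ap[1, 2] <- Ap[2, 1] <- Ap[2, 3] <- Ap[3, 2] <- 1
  lap <- graph_laplacian(Ap)
  expect_equal(diag(lap$D), c(1, 2, 1))
  expect_equal(lap$L, matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3))

  for (s in 1:10) {
    n <- 8
    Ap <- withr::with_seed(s, {
      M <- matrix(stats::rbinom(n * n, 1, 0.4), n, n)
      M[lower.tri(M)] <- t(M)[lower.tri(M)]
      diag(M) <- 0
      M
    })
    L <- graph_laplacian(Ap)$L
    expect_equal(unname(rowSums(L)), rep(0, n))
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
})

test_that("the objective matches its closed forms and a scalar-loop oracle", {
  sim <- planted_partition(c(6, 6), 0.6, 0.1, seed = 3)
  sg <- encode_signed(sim$network, NULL)
  H0 <- matrix(0, 12, 2)
  expect_equal(sscd_objective(sg, H0, 0, 0), 2 * n_edges(sim$network))

  H <- cbind(c(rep(0.8, 6), rep(0, 6)), c(rep(0, 6), rep(0.8, 6)))
  A <- H %*% t(H)
  net <- sscd:::new_network(paste0("n", 1:12), A)  # exact factorization target
  sg2 <- structure(list(network = net, positive = sg$positive, negative = sg$negative),
                   class = "sscd_signed")
  expect_equal(sscd_objective(sg2, H, 0, 0), 0)

  for (s in 1:8) {
    inst <- rand_instance(8, p = 0.4, seed = s)
    cs <- sample_constraints(inst$truth, 0.3, 0.3, seed = s)
    sg <- encode_signed(inst$network, cs)
    H <- withr::with_seed(s + 50, matrix(stats::runif(8 * 3), 8, 3))
    g1 <- c(0.5, 2)[s %% 2 + 1]
    g2 <- c(1, 0.3)[s %% 2 + 1]
    expect_equal(sscd_objective(sg, H, g1, g2),
                 oracle_objective(as_adjacency(inst$network), sg$positive,
                                  sg$negative, H, g1, g2),
                 tolerance = 1e-10)
  }
})

test_that("one multiplicative update matches the hand-evaluated rule", {
  net <- sscd:::new_network(c("a", "b"), matrix(c(0, 1, 1, 0), 2, 2))
  sg <- encode_signed(net, NULL)
  H <- matrix(c(1, 1), 2, 1)
  H1 <- sscd_update(H, sg, gamma1 = 0, gamma2 = 0)
  expect_equal(unname(H1), matrix(c(0.5, 0.5), 2, 1))
})

test_that("a KKT-satisfying factorization is an exact fixed point", {
  H <- cbind(c(0.7, 0.7, 0, 0), c(0, 0, 0.5, 0.5))
  A <- H %*% t(H)  # gradient -4AH + 4HH'H vanishes exactly
  net <- sscd:::new_network(paste0("n", 1:4), A)
  sg <- encode_signed(net, NULL)
  H1 <- sscd_update(H, sg, gamma1 = 0, gamma2 = 0)
  expect_lt(max(abs(H1 - H)), 1e-12)
})

test_that("nonnegativity survives long update sequences on random signed instances", {
  for (s in 1:5) {
    inst <- rand_instance(20, p = 0.25, kt = 3, seed = s)
    cs <- sample_constraints(inst$truth, 0.2, 0.2, seed = s)
    sg <- encode_signed(inst$network, cs)
    D <- graph_laplacian(sg$positive)$D
    H <- withr::with_seed(s, matrix(stats::runif(20 * 3, 0.01, 1), 20, 3))
    for (i in 1:100) {
      H <- sscd_update(H, sg, D, gamma1 = 1.5, gamma2 = 0.7)
      expect_true(all(H >= 0))
      expect_true(all(is.finite(H)))
    }
  }
})

test_that("the numeric gradient of the objective matches the analytic form", {
  # analytic: -4AH + 4HH'H + 2 g1 An H + 2 g2 L H
  for (s in 1:5) {
    inst <- rand_instance(5, p = 0.5, seed = s)
    cs <- sample_constraints(inst$truth, 0.5, 0.5, seed = s)
    sg <- encode_signed(inst$network, cs)
    A <- as_adjacency(inst$network)
    L <- graph_laplacian(sg$positive)$L
    g1 <- 0.8; g2 <- 1.3
    H <- withr::with_seed(s + 9, matrix(stats::runif(5 * 2, 0.2, 1), 5, 2))
    analytic <- -4 * A %*% H + 4 * H %*% crossprod(H) +
      2 * g1 * sg$negative %*% H + 2 * g2 * L %*% H
    h <- 1e-6
    numeric <- H * 0
    for (i in 1:5) {
      for (j in 1:2) {
        Hp <- H; Hp[i, j] <- Hp[i, j] + h
        Hm <- H; Hm[i, j] <- Hm[i, j] - h
        numeric[i, j] <- (sscd_objective(sg, Hp, g1, g2) -
                          sscd_objective(sg, Hm, g1, g2)) / (2 * h)
      }
    }
    expect_lt(max(abs(numeric - analytic)), 1e-5)
  }
})

test_that("with both penalties off the fit IS plain symmetric NMF, iteration for iteration", {
  sim <- planted_partition(c(8, 8), 0.5, 0.1, seed = 13)
  A <- as_adjacency(sim$network)
  n <- nrow(A); k <- 2; seed <- 21
  fit <- sscd_fit(sim$network, k = k, gamma1 = 0, gamma2 = 0, seed = seed,
                  max_iter = 40, tol = 1e-15)
  H <- withr::with_seed(seed, matrix(stats::runif(n * k, 0.01, 1), n, k))
  for (i in seq_len(fit$n_iter)) H <- plain_symnmf_step(H, A)
  expect_equal(unname(fit$H), unname(H), tolerance = 1e-12)
})

test_that("an easy planted partition is recovered exactly without priors", {
  sim <- planted_partition(c(20, 20), p_in = 0.5, p_out = 0.02, seed = 1)
  fit <- sscd_fit(sim$network, k = 2, seed = 1)
  expect_equal(nmi(hard_assign(fit), sim$truth), 1)
  expect_true(all(fit$H >= 0))
})

test_that("fit validates k and records a trace and metadata", {
  sim <- planted_partition(c(5, 5), 0.8, 0.1, seed = 2)
  expect_error(sscd_fit(sim$network, k = 11, seed = 1), "exceeds")
  expect_error(sscd_fit(sim$network, k = 0, seed = 1), "k must be")
  fit <- sscd_fit(sim$network, k = 2, seed = 5)
  expect_equal(length(fit$objective_trace), fit$n_iter + 1)
  expect_true(is.logical(fit$converged))
  g <- glance(fit)
  expect_equal(g$n, 10)
  expect_equal(g$objective, utils::tail(fit$objective_trace, 1))
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_true(all(c("node", "community", "h1", "h2") %in% names(td)))
})

test_that("hardening takes the row argmax with ties to the lowest column", {
  H <- rbind(c(0.1, 0.9), c(0.5, 0.5), c(0.9, 0.1))
  rownames(H) <- c("a", "b", "c")
  p <- hard_assign(H)
  # argmax communities: 2, 1 (tie), 1 -> renumbered by first appearance
  expect_equal(p$community[p$node == "b"], p$community[p$node == "c"])
  expect_true(p$community[p$node == "a"] != p$community[p$node == "b"])

  expect_warning(pz <- hard_assign(rbind(c(0, 0), c(1, 0))), "all-zero")
  expect_equal(pz$community, c(1L, 1L))
})

test_that("hardening is invariant to positive row rescaling", {
  for (s in 1:10) {
    H <- withr::with_seed(s, matrix(stats::runif(24), 8, 3))
    scales <- withr::with_seed(s + 1, stats::runif(8, 0.1, 10))
    expect_equal(hard_assign(H), hard_assign(H * scales))
  }
})

test_that("per-update cost scales roughly quadratically in n", {
  time_updates <- function(n, reps = 40) {
    sim <- planted_partition(c(n / 2, n / 2), 0.05, 0.02, seed = 1)
    sg <- encode_signed(sim$network, NULL)
    D <- graph_laplacian(sg$positive)$D
    H <- withr::with_seed(2, matrix(stats::runif(n * 4, 0.01, 1), n, 4))
    best <- Inf
    for (trial in 1:3) {
      t0 <- proc.time()[3]
      for (i in seq_len(reps)) invisible(sscd_update(H, sg, D))
      best <- min(best, proc.time()[3] - t0)
    }
    best
  }
  ratio <- time_updates(1200) / time_updates(600)
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 6)
})
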