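#' Generate a planted-partition network with ground truth
#'
#' Nodes are split into blocks of the given sizes; each intra-block pair
#' is an edge independently with probability `p_in`, each inter-block
#' pair with `p_out`. Assortative fixtures require `p_out <= p_in`
#' (override with `allow_disassortative`). Deterministic given `seed`.
#'
#' @param block_sizes Positive integer sizes of the planted blocks.
#' @param p_in,p_out Within- / between-block edge probabilities.
#' @param seed Integer seed (`NULL`: current RNG state).
#' @param allow_disassortative Permit `p_out > p_in`.
#' @return List with `network` (`sscd_network`, nodes `"n1".."nN"`) and
#'   `truth` (partition tibble).
#' @examples
#' sim <- planted_partition(c(3, 3), p_in = 1, p_out = 0, seed = 1)
#' n_edges(sim$network)  # two disjoint triangles: 6 edges
#' @export
planted_partition <- function(block_sizes, p_in, p_out, seed = NULL,
                              allow_disassortative = FALSE) {
  stopifnot(all(block_sizes >= 1), p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  n <- sum(block_sizes)
  if (n < 2) rlang::abort("need at least 2 nodes")
  if (p_out > p_in && !allow_disassortative) {
    rlang::abort("p_out > p_in rejected for assortative fixtures (set allow_disassortative = TRUE)")
  }
  g <- rep(seq_along(block_sizes), block_sizes)
  draw <- function() {
    same <- outer(g, g, "==")
    p <- ifelse(same, p_in, p_out)
    u <- matrix(0, n, n)
    ut <- upper.tri(u)
    u[ut] <- stats::runif(sum(ut))
    A <- matrix(0, n, n)
    A[ut] <- as.numeric(u[ut] < p[ut])
    A + t(A)
  }
  A <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  nodes <- paste0("n", seq_len(n))
  list(network = new_network(nodes, A),
       truth = as_partition(tibble::tibble(node = nodes, community = g)))
}

#' Flip the type of a random subset of constraints
#'
#' Swaps must <-> cannot for `floor(flip_fraction * nrow(cs))` pairs
#' chosen uniformly, emulating incorrect prior knowledge.
#'
#' @param cs A constraint tibble.
#' @param flip_fraction Fraction in `[0, 1]` of pairs to flip.
#' @param seed Integer seed.
#' @return A constraint tibble with attribute `provenance = "corrupted"`.
#' @export
corrupt_constraints <- function(cs, flip_fraction, seed = NULL) {
  stopifnot(flip_fraction >= 0, flip_fraction <= 1)
  n_flip <- floor(flip_fraction * nrow(cs))
  pick <- function() sample.int(nrow(cs), n_flip)
  idx <- if (n_flip == 0) integer() else if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  out <- tibble::as_tibble(cs)
  out$type[idx] <- ifelse(out$type[idx] == "must", "cannot", "must")
  new_constraints(out, seed = seed, provenance = "corrupted")
}

#' Write a versioned suite of planted-partition fixtures
#'
#' Emits three regimes under `path/<regime>/`: `easy` (2 blocks of 20,
#' p_in 0.5, p_out 0.02 — recoverable from topology alone), `ambiguous`
#' (3 blocks of 40, p_in 0.12, p_out 0.08 — below the detectability
#' threshold, where priors matter) and `unbalanced` (blocks 60/30/15,
#' p_in 0.3, p_out 0.05). Each regime gets `edges.tsv`, `labels.tsv`,
#' and the suite a `manifest.json` recording parameters and seeds.
#'
#' @param path Writable directory (created if missing).
#' @param seed Base seed; regime `r` uses a seed derived from it.
#' @return Invisibly, the manifest as a list.
#' @export
fixture_suite <- function(path, seed = 20170523) {
  regimes <- list(
    easy = list(block_sizes = c(20, 20), p_in = 0.5, p_out = 0.02),
    ambiguous = list(block_sizes = c(40, 40, 40), p_in = 0.12, p_out = 0.08),
    unbalanced = list(block_sizes = c(60, 30, 15), p_in = 0.3, p_out = 0.05)
  )
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(version = 1L, seed = seed, regimes = list())
  for (nm in names(regimes)) {
    rg <- regimes[[nm]]
    rg_seed <- derive_seed(seed, nm)
    sim <- planted_partition(rg$block_sizes, rg$p_in, rg$p_out, seed = rg_seed)
    dir.create(file.path(path, nm), showWarnings = FALSE)
    write_edge_list(sim$network, file.path(path, nm, "edges.tsv"))
    utils::write.table(as.data.frame(sim$truth), file.path(path, nm, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    manifest$regimes[[nm]] <- c(rg, seed = rg_seed,
                                n = sum(rg$block_sizes),
                                edges = n_edges(sim$network))
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
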