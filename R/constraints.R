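#' Prior budgets: maximum numbers of must-link and cannot-link pairs
#'
#' For ground-truth community sizes \eqn{N_1,\dots,N_K} over \eqn{n}
#' nodes, the must-link budget is \eqn{M = \sum_k N_k (N_k - 1)/2} (all
#' intra-community pairs) and the cannot-link budget is
#' \eqn{C = \sum_{i<j} N_i N_j} (all inter-community pairs). The two sum
#' to \eqn{n(n-1)/2}. Prior percentages are always taken relative to
#' these budgets.
#'
#' @param partition A partition tibble (see [as_partition()]).
#' @return A count (numeric, exact for any realistic `n`).
#' @export
max_must_pairs <- function(partition) {
  sizes <- as.numeric(table(as_partition(partition)$community))
  sum(sizes * (sizes - 1) / 2)
}

#' @rdname max_must_pairs
#' @export
max_cannot_pairs <- function(partition) {
  sizes <- as.numeric(table(as_partition(partition)$community))
  (sum(sizes)^2 - sum(sizes^2)) / 2
}

#' Sample pairwise constraints from a ground-truth partition
#'
#' Draws `floor(pct_must * M)` must-link pairs uniformly without
#' replacement from all intra-community pairs and
#' `floor(pct_cannot * C)` cannot-link pairs from all inter-community
#' pairs, where `M` and `C` are the budgets of [max_must_pairs()] /
#' [max_cannot_pairs()]. Intra-community pairs already joined by a
#' topological edge are eligible: the budget counts all intra pairs.
#'
#' @param partition A partition tibble.
#' @param pct_must,pct_cannot Fractions in `[0, 1]` of the respective
#'   budgets.
#' @param seed Integer seed; sampling is deterministic given it. `NULL`
#'   uses the current RNG state.
#' @return A constraint set: tibble with columns `node_a`, `node_b`,
#'   `type` (`"must"` / `"cannot"`), with `node_a < node_b` in node-index
#'   order under `partition`, plus attributes `seed` and `provenance`.
#' @export
sample_constraints <- function(partition, pct_must = 0, pct_cannot = 0, seed = NULL) {
  partition <- as_partition(partition)
  stopifnot(pct_must >= 0, pct_must <= 1, pct_cannot >= 0, pct_cannot <= 1)
  g <- partition$community
  n <- length(g)
  same <- outer(g, g, "==")
  ut <- upper.tri(same)
  intra <- which(same & ut, arr.ind = TRUE)
  inter <- which(!same & ut, arr.ind = TRUE)
  n_must <- floor(pct_must * nrow(intra))
  n_cannot <- floor(pct_cannot * nrow(inter))
  draw <- function() {
    mi <- if (n_must > 0) intra[sample.int(nrow(intra), n_must), , drop = FALSE] else intra[0, , drop = FALSE]
    ci <- if (n_cannot > 0) inter[sample.int(nrow(inter), n_cannot), , drop = FALSE] else inter[0, , drop = FALSE]
    list(mi, ci)
  }
  picks <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  cs <- tibble::tibble(
    node_a = partition$node[c(picks[[1]][, 1], picks[[2]][, 1])],
    node_b = partition$node[c(picks[[1]][, 2], picks[[2]][, 2])],
    type = rep(c("must", "cannot"), c(nrow(picks[[1]]), nrow(picks[[2]])))
  )
  new_constraints(cs, seed = seed, provenance = "sampled")
}

new_constraints <- function(tbl, seed = NULL, provenance = "user") {
  tbl <- tibble::as_tibble(tbl)[c("node_a", "node_b", "type")]
  bad <- setdiff(unique(tbl$type), c("must", "cannot"))
  if (length(bad)) rlang::abort(sprintf("unknown constraint type: %s", paste(bad, collapse = ", ")))
  if (any(tbl$node_a == tbl$node_b)) rlang::abort("constraint pairs (i, i) are not allowed")
  key <- paste(pmin(tbl$node_a, tbl$node_b), pmax(tbl$node_a, tbl$node_b))
  both <- intersect(key[tbl$type == "must"], key[tbl$type == "cannot"])
  if (length(both)) {
    rlang::abort(sprintf("pair(s) marked both must and cannot: %s",
                         paste(utils::head(both, 5), collapse = "; ")))
  }
  tbl <- tbl[!duplicated(key), ]
  structure(tbl, seed = seed, provenance = provenance,
            class = c("sscd_constraints", class(tbl)))
}

#' Read / write a constraint file
#'
#' Three-column TSV: `node_a`, `node_b`, `type` with type in
#' `{must, cannot}`.
#'
#' @param path Path to the constraint file.
#' @return `read_constraints()`: a constraint tibble;
#'   `write_constraints()`: `path`, invisibly.
#' @export
read_constraints <- function(path) {
  lines <- readLines(path)
  keep <- which(trimws(sub("#.*$", "", lines)) != "")
  if (length(keep) == 0) {
    return(new_constraints(tibble::tibble(node_a = character(), node_b = character(),
                                          type = character())))
  }
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(toks) != 3)) {
    bad <- keep[which(lengths(toks) != 3)[1]]
    rlang::abort(sprintf("malformed constraint at line %d of '%s': expected (node_a, node_b, type)", bad, path))
  }
  new_constraints(tibble::tibble(node_a = vapply(toks, `[`, "", 1),
                                 node_b = vapply(toks, `[`, "", 2),
                                 type = vapply(toks, `[`, "", 3)))
}

#' @rdname read_constraints
#' @param constraints A constraint tibble.
#' @export
write_constraints <- function(constraints, path) {
  utils::write.table(as.data.frame(constraints)[c("node_a", "node_b", "type")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Encode constraints as a signed network
#'
#' Builds the positive-link matrix \eqn{A^p} (1 exactly at must-link
#' pairs, both orientations) and the negative-link matrix \eqn{A^n}
#' (1 exactly at cannot-link pairs) over the node set of `network`. The
#' topology `A` passes through unchanged: objective and update treat
#' `A` and `A^p` as distinct terms. Set `fold_topology = TRUE` to also
#' add the original edges to `A^p`.
#'
#' @param network An `sscd_network`.
#' @param constraints A constraint tibble (may be empty or `NULL`).
#' @param fold_topology If `TRUE`, original edges are added as positive
#'   links. Default `FALSE`.
#' @return An `sscd_signed` object: list with `network`, `positive`,
#'   `negative` (both symmetric binary matrices, zero diagonal).
#' @export
encode_signed <- function(network, constraints = NULL, fold_topology = FALSE) {
  n <- n_nodes(network)
  Ap <- matrix(0, n, n, dimnames = dimnames(network$adjacency))
  An <- Ap
  if (!is.null(constraints) && nrow(constraints) > 0) {
    constraints <- new_constraints(constraints,
                                   seed = attr(constraints, "seed"),
                                   provenance = attr(constraints, "provenance") %||% "user")
    ia <- match(constraints$node_a, network$nodes)
    ib <- match(constraints$node_b, network$nodes)
    if (anyNA(ia) || anyNA(ib)) {
      miss <- unique(c(constraints$node_a[is.na(ia)], constraints$node_b[is.na(ib)]))
      rlang::abort(sprintf("constraint node(s) not in network: %s",
                           paste(utils::head(miss, 5), collapse = ", ")))
    }
    m <- constraints$type == "must"
    Ap[cbind(ia[m], ib[m])] <- 1; Ap[cbind(ib[m], ia[m])] <- 1
    An[cbind(ia[!m], ib[!m])] <- 1; An[cbind(ib[!m], ia[!m])] <- 1
  }
  if (fold_topology) Ap <- pmax(Ap, network$adjacency)
  structure(list(network = network, positive = Ap, negative = An),
            class = "sscd_signed")
}

#' @export
print.sscd_signed <- function(x, ...) {
  cat(sprintf("<sscd_signed> %d nodes, %d edges, %d positive links, %d negative links\n",
              n_nodes(x$network), n_edges(x$network),
              sum(x$positive) / 2, sum(x$negative) / 2))
  invisible(x)
}
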