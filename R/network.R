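#' Construct an undirected, unweighted network
#'
#' A network is a set of opaque node identifiers plus a symmetric binary
#' adjacency matrix with zero diagonal. Edges are deduplicated,
#' symmetrized, and self-loops are dropped. Node order is first-appearance
#' order in `edges` (then `nodes`), and all matrices produced downstream
#' (constraint encodings, Laplacians, factor matrices) are indexed in this
#' order.
#'
#' @param edges A data frame whose first two columns are node identifiers
#'   of the endpoints, one row per edge. Extra columns (e.g. weights) are
#'   ignored with a warning: the model is binary.
#' @param nodes Optional character vector of node identifiers to include
#'   even if they carry no edge (isolated nodes). Identifiers appearing
#'   in `edges` but not in `nodes` are kept too.
#' @return An object of class `sscd_network`.
#' @examples
#' net <- as_network(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
#' net
#' @export
as_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) > 2) {
    rlang::warn("edge table has more than 2 columns; extras (e.g. weights) are ignored: the model is binary")
    edges <- edges[, 1:2, drop = FALSE]
  }
  if (ncol(edges) < 2) rlang::abort("edge table needs two endpoint columns")
  from <- as.character(edges[[1]])
  to <- as.character(edges[[2]])
  ids <- unique(c(rbind(from, to), as.character(nodes %||% character())))
  n <- length(ids)
  adj <- matrix(0, n, n, dimnames = list(ids, ids))
  i <- match(from, ids)
  j <- match(to, ids)
  keep <- i != j
  adj[cbind(i[keep], j[keep])] <- 1
  adj[cbind(j[keep], i[keep])] <- 1
  new_network(ids, adj)
}

# low-level constructor; `adjacency` must already satisfy the invariants
new_network <- function(node_ids, adjacency) {
  stopifnot(length(node_ids) == nrow(adjacency), nrow(adjacency) == ncol(adjacency))
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(list(nodes = as.character(node_ids), adjacency = adjacency),
            class = "sscd_network")
}

validate_network <- function(net) {
  A <- net$adjacency
  if (!isSymmetric(unname(A))) rlang::abort("adjacency must be symmetric")
  if (any(diag(A) != 0)) rlang::abort("adjacency must have zero diagonal")
  if (!all(A %in% c(0, 1))) rlang::abort("adjacency entries must be 0 or 1")
  net
}

#' Number of nodes / edges of a network
#' @param network An `sscd_network`.
#' @return Integer count.
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) as.integer(sum(network$adjacency) / 2)

#' Adjacency matrix of a network
#' @param network An `sscd_network`.
#' @return A symmetric binary matrix with node identifiers as dimnames.
#' @export
as_adjacency <- function(network) network$adjacency

#' @export
as.data.frame.sscd_network <- function(x, ...) as.data.frame(edge_tbl(x))

#' Edge table of a network
#'
#' @param network An `sscd_network`.
#' @return A tibble with columns `from`, `to` (one row per undirected
#'   edge, endpoints ordered by node index).
#' @export
edge_tbl <- function(network) {
  A <- network$adjacency
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  tibble::tibble(from = network$nodes[idx[, 1]], to = network$nodes[idx[, 2]])
}

#' @export
print.sscd_network <- function(x, ...) {
  cat(sprintf("<sscd_network> %d nodes, %d edges\n", n_nodes(x), n_edges(x)))
  invisible(x)
}

#' Add isolated nodes to a network
#'
#' Nodes present in a label file but absent from the edge file enter the
#' network with degree 0, so metrics stay defined over all n nodes.
#'
#' @param network An `sscd_network`.
#' @param nodes Character vector of node identifiers; those already
#'   present are ignored.
#' @return An `sscd_network` over the union of the node sets.
#' @export
add_isolated_nodes <- function(network, nodes) {
  extra <- setdiff(as.character(nodes), network$nodes)
  if (length(extra) == 0) return(network)
  n0 <- n_nodes(network)
  ids <- c(network$nodes, extra)
  A <- matrix(0, length(ids), length(ids))
  A[seq_len(n0), seq_len(n0)] <- network$adjacency
  new_network(ids, A)
}
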