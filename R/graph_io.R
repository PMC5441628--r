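#' Read a network from a whitespace-separated edge list
#'
#' One edge per line: two node tokens separated by whitespace or tabs.
#' Lines starting with `#` are comments. Duplicate and reciprocal edges
#' collapse to one undirected edge; self-loops are dropped. A third
#' column (weights) is tolerated and ignored with a warning.
#'
#' @param path Path to the edge-list file.
#' @return An `sscd_network`. Node order is first-appearance order.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  keep <- which(trimws(stripped) != "")
  if (length(keep) == 0) rlang::abort(sprintf("no edges found in '%s'", path))
  toks <- strsplit(trimws(stripped[keep]), "[ \t]+")
  nt <- lengths(toks)
  if (any(nt != 2 & nt != 3)) {
    bad <- keep[which(nt != 2 & nt != 3)[1]]
    rlang::abort(sprintf("malformed edge at line %d of '%s': expected 2 node tokens", bad, path))
  }
  if (any(nt == 3)) {
    rlang::warn(sprintf("'%s' has a third column; treated as weights and ignored (binary model)", path))
  }
  as_network(data.frame(from = vapply(toks, `[`, "", 1),
                        to = vapply(toks, `[`, "", 2)))
}

#' Write a network as a tab-separated edge list
#'
#' Isolated nodes cannot be represented in an edge list; use
#' [write_gml()] when they must round-trip.
#'
#' @param network An `sscd_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path) {
  et <- edge_tbl(network)
  utils::write.table(et, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a network in GML format
#'
#' Thin wrappers over [igraph::read_graph()] / [igraph::write_graph()].
#' Directed or duplicated edges are symmetrized and deduplicated; node
#' identity is the GML `label` if present, else the `id`.
#'
#' @param path Path to the GML file.
#' @return `read_gml()`: an `sscd_network`. `write_gml()`: `path`, invisibly.
#' @export
read_gml <- function(path) {
  g <- tryCatch(igraph::read_graph(path, format = "gml"),
                error = function(e) rlang::abort(sprintf("cannot parse GML '%s': %s", path, conditionMessage(e))))
  g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  va <- igraph::vertex_attr_names(g)
  ids <- if ("label" %in% va) {
    as.character(igraph::vertex_attr(g, "label"))
  } else if ("id" %in% va) {
    as.character(igraph::vertex_attr(g, "id"))
  } else {
    as.character(seq_len(igraph::vcount(g)))
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A[A > 0] <- 1
  validate_network(new_network(ids, A))
}

#' @rdname read_gml
#' @param network An `sscd_network`.
#' @export
write_gml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
  igraph::V(g)$label <- network$nodes
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Read ground-truth community labels
#'
#' Expects a two-column TSV of `(node_id, community_label)`. Labels are
#' opaque tokens; they are mapped to community indices `1..k` in order
#' of first appearance.
#'
#' @param path Path to the label file.
#' @return A partition: a tibble with columns `node` (character) and
#'   `community` (integer in `1..k`).
#' @export
read_labels <- function(path) {
  lines <- readLines(path)
  keep <- which(trimws(sub("#.*$", "", lines)) != "")
  if (length(keep) == 0) rlang::abort(sprintf("no labels found in '%s'", path))
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  if (any(lengths(toks) != 2)) {
    bad <- keep[which(lengths(toks) != 2)[1]]
    rlang::abort(sprintf("malformed label at line %d of '%s': expected (node, label)", bad, path))
  }
  node <- vapply(toks, `[`, "", 1)
  lab <- vapply(toks, `[`, "", 2)
  dup <- tapply(lab, node, function(x) length(unique(x)) > 1)
  if (any(dup)) {
    rlang::abort(sprintf("node(s) labelled twice with different labels: %s",
                         paste(names(dup)[dup], collapse = ", ")))
  }
  first <- !duplicated(node)
  as_partition(tibble::tibble(node = node[first],
                              community = match(lab[first], unique(lab[first]))))
}

#' Coerce to a partition tibble
#'
#' A partition assigns every node to exactly one of `k` communities. It
#' is represented as a tibble with columns `node` (character) and
#' `community` (integer `1..k`, renumbered by first appearance).
#'
#' @param x A data frame with node / community columns, or a vector of
#'   community labels named by node.
#' @return A partition tibble.
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("node", "community") %in% names(x))) {
      if (ncol(x) < 2) rlang::abort("partition needs node and community columns")
      names(x)[1:2] <- c("node", "community")
    }
    node <- as.character(x$node)
    lab <- x$community
  } else {
    if (is.null(names(x))) rlang::abort("partition vector must be named by node")
    node <- names(x)
    lab <- unname(x)
  }
  if (anyDuplicated(node)) rlang::abort("duplicate node in partition")
  tibble::tibble(node = node, community = as.integer(match(lab, unique(lab))))
}

# integer community vector aligned to `nodes` (errors if any node missing)
partition_vec <- function(partition, nodes) {
  idx <- match(nodes, partition$node)
  if (anyNA(idx)) {
    rlang::abort(sprintf("nodes missing from partition: %s",
                         paste(utils::head(nodes[is.na(idx)], 5), collapse = ", ")))
  }
  partition$community[idx]
}

#' Write a detection report
#'
#' Writes the membership as a two-column TSV `(node_id, community)` and a
#' JSON sidecar (same basename, `.json` extension) holding the metrics,
#' hyperparameters, seed, iteration count and objective trace. The
#' sidecar object has fields `metrics` (name -> value), `hyperparams`,
#' `seed`, `n_iter`, `converged` and `objective_trace`.
#'
#' @param partition A partition tibble (see [as_partition()]).
#' @param path Output path for the membership TSV.
#' @param metrics Named list/vector of metric values.
#' @param trace Numeric vector of objective values per iteration.
#' @param hyperparams Named list of hyperparameters used for the fit.
#' @param seed Seed used, or `NULL`.
#' @param n_iter Iterations run, or `NULL`.
#' @param converged Logical convergence flag, or `NULL`.
#' @return Invisibly, the sidecar path.
#' @export
write_report <- function(partition, path, metrics = list(), trace = numeric(),
                         hyperparams = list(), seed = NULL, n_iter = NULL,
                         converged = NULL) {
  partition <- as_partition(partition)
  utils::write.table(partition, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- paste0(sub("\\.[^./]*$", "", path), ".json")
  payload <- list(metrics = as.list(metrics),
                  hyperparams = as.list(hyperparams),
                  seed = seed, n_iter = n_iter, converged = converged,
                  objective_trace = as.numeric(trace))
  jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Read back a detection report
#'
#' @param path Path to the membership TSV written by [write_report()].
#' @return A list with `partition` (tibble) and `report` (parsed sidecar).
#' @export
read_report <- function(path) {
  part <- read_labels(path)
  side <- paste0(sub("\\.[^./]*$", "", path), ".json")
  rep <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  list(partition = part, report = rep)
}
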