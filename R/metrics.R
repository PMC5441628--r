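#' Confusion matrix of two partitions
#'
#' `F[i, j]` counts the nodes placed in community `i` of `detected` that
#' carry label `j` in `truth`. Both partitions must cover the same node
#' set; rows/columns of empty communities are absent.
#'
#' @param detected,truth Partition tibbles (see [as_partition()]) over
#'   the same nodes.
#' @return An integer matrix whose entries sum to the number of nodes.
#' @export
confusion <- function(detected, truth) {
  detected <- as_partition(detected)
  truth <- as_partition(truth)
  if (!setequal(detected$node, truth$node)) {
    rlang::abort("detected and truth partitions cover different node sets")
  }
  g <- partition_vec(truth, detected$node)
  unclass(table(detected$community, g))
}

#' Normalized mutual information between two partitions
#'
#' \deqn{\mathrm{NMI}(C,G) = \frac{-2 \sum_{ij} F_{ij}
#'   \log\!\big(F_{ij} n / (F_{i\cdot} F_{\cdot j})\big)}
#'   {\sum_i F_{i\cdot}\log(F_{i\cdot}/n) + \sum_j F_{\cdot j}\log(F_{\cdot j}/n)}}
#' with the convention \eqn{0 \log 0 = 0}. Equals 1 for identical
#' partitions and 0 for independent ones; symmetric in its arguments and
#' invariant to community relabelling. If both partitions are trivial
#' (one community each) the denominator vanishes; the value is then
#' defined as 1 (they are equal) with a warning.
#'
#' @inheritParams confusion
#' @return A value in `[0, 1]`.
#' @export
nmi <- function(detected, truth) {
  Fm <- confusion(detected, truth)
  n <- sum(Fm)
  ri <- rowSums(Fm)
  cj <- colSums(Fm)
  den <- sum(ri * log(ri / n)) + sum(cj * log(cj / n))
  if (den == 0) {
    same <- nrow(Fm) == 1 && ncol(Fm) == 1
    rlang::warn("both partitions are trivial; NMI defined as 1 if equal, else 0")
    return(if (same) 1 else 0)
  }
  E <- outer(ri, cj) / n
  terms <- ifelse(Fm > 0, Fm * log(Fm / E), 0)
  -2 * sum(terms) / den
}

#' Purity of a detected partition
#'
#' \deqn{\mathrm{Purity} = \frac{1}{n} \sum_i \max_j |C_i \cap G_j|}:
#' each detected community votes for its majority ground-truth label.
#' Never decreases when a detected community is split.
#'
#' @inheritParams confusion
#' @return A value in `(0, 1]`.
#' @export
purity <- function(detected, truth) {
  Fm <- confusion(detected, truth)
  sum(apply(Fm, 1, max)) / sum(Fm)
}
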