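#' @importFrom rlang %||%
#' @importFrom generics tidy glance
NULL

# deterministic 31-bit seed derived from a master seed and a sequence of
# keys (integers or strings); keeps every derived seed inside R's
# integer range so downstream set.seed() calls are portable.
derive_seed <- function(master, ...) {
  mod <- 2147483647
  keys <- list(...)
  lens <- vapply(keys, length, 0L)
  n_out <- max(1L, max(lens))
  out <- numeric(n_out)
  for (r in seq_len(n_out)) {
    h <- (as.numeric(master) %% mod + 11) %% mod
    for (kk in keys) {
      v <- kk[[min(r, length(kk))]]
      codes <- if (is.character(v)) utf8ToInt(v) else as.numeric(v) %% mod + 1
      for (cd in codes) h <- (h * 48271 + cd + 1) %% mod
    }
    h <- (h * 48271 + r) %% mod
    out[r] <- h %% (mod - 2) + 1
  }
  as.integer(out)
}

#' @export
tidy.sscd_fit <- function(x, ...) {
  H <- x$H
  soft <- tibble::as_tibble(H, .name_repair = ~ paste0("h", seq_len(ncol(H))))
  dplyr::bind_cols(hard_assign(x), soft)
}

#' @export
glance.sscd_fit <- function(x, ...) {
  tibble::tibble(method = x$method,
                 n = nrow(x$H), k = ncol(x$H),
                 objective = utils::tail(x$objective_trace, 1),
                 n_iter = x$n_iter,
                 converged = x$converged,
                 n_communities = length(unique(hard_assign(x)$community)))
}

#' Plot the objective trace of a fit
#'
#' @param object An `sscd_fit`.
#' @param ... Ignored.
#' @return A ggplot of objective value against iteration.
#' @export
autoplot.sscd_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$objective_trace) - 1,
                       objective = object$objective_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "objective",
                  title = sprintf("%s fit (n = %d, k = %d)",
                                  object$method, nrow(object$H), ncol(object$H))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance
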