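#' Prior-percentage sweep over detection methods
#'
#' Re-runs each method at each prior percentage with freshly sampled
#' constraints and a fresh initialization per run (run `r` of a cell uses
#' a seed derived from `seed`, the method, the percentage and `r`), then
#' aggregates NMI and Purity across runs. Percentages are fractions of
#' the must-link / cannot-link budgets of [max_must_pairs()] /
#' [max_cannot_pairs()]; with `mix = "half_half"` a total prior level
#' `p` is split as `p/2` of each budget.
#'
#' @param network An `sscd_network`.
#' @param truth Ground-truth partition tibble.
#' @param k Number of communities (default: number of truth communities).
#' @param methods Character subset of
#'   `c("sscd", "nmf_lse", "pmf", "snmf_ss")`.
#' @param percentages Prior levels in `[0, 1]`.
#' @param mix `"must_only"`, `"cannot_only"` or `"half_half"`.
#' @param runs Repeats per cell (study default 50).
#' @param seed Master seed; the whole sweep is reproducible from it.
#' @param gamma1,gamma2 Weights for the `"sscd"` method.
#' @param ... Further arguments for the fitters (`max_iter`, `tol`, ...).
#' @return An `sscd_sweep` tibble: one row per method x percentage with
#'   `nmi_mean`, `nmi_var`, `purity_mean`, `purity_var`, `runs`, plus any
#'   per-cell error count in `failed`.
#' @export
prior_sweep <- function(network, truth, k = NULL,
                        methods = c("sscd", "nmf_lse", "pmf", "snmf_ss"),
                        percentages = c(0, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                        mix = c("must_only", "cannot_only", "half_half"),
                        runs = 50, seed = 1, gamma1 = 1, gamma2 = 1, ...) {
  mix <- match.arg(mix)
  truth <- as_partition(truth)
  k <- k %||% max(truth$community)
  stopifnot(all(percentages >= 0), all(percentages <= 1), runs >= 1)
  grid <- tidyr::expand_grid(method = methods, percentage = percentages)
  cells <- purrr::pmap(grid, function(method, percentage) {
    pm <- switch(mix, must_only = percentage, cannot_only = 0, half_half = percentage / 2)
    pc <- switch(mix, must_only = 0, cannot_only = percentage, half_half = percentage / 2)
    res <- purrr::map(seq_len(runs), function(r) {
      s <- derive_seed(seed, method, round(percentage * 1000), r)
      tryCatch({
        cs <- sample_constraints(truth, pct_must = pm, pct_cannot = pc,
                                 seed = derive_seed(s, "constraints"))
        fit <- if (method == "sscd") {
          sscd_fit(network, k = k, constraints = cs,
                   gamma1 = gamma1, gamma2 = gamma2, seed = s, ...)
        } else {
          fit_method(method, network, k = k, constraints = cs, seed = s, ...)
        }
        part <- hard_assign(fit)
        c(nmi = nmi(part, truth), purity = purity(part, truth))
      }, error = function(e) c(nmi = NA_real_, purity = NA_real_))
    })
    m <- do.call(rbind, res)
    tibble::tibble(nmi_mean = mean(m[, "nmi"], na.rm = TRUE),
                   nmi_var = stats::var(m[, "nmi"], na.rm = TRUE),
                   purity_mean = mean(m[, "purity"], na.rm = TRUE),
                   purity_var = stats::var(m[, "purity"], na.rm = TRUE),
                   runs = runs, failed = sum(is.na(m[, "nmi"])))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  out$mix <- mix
  structure(out, class = c("sscd_sweep", class(out)),
            sweep_type = "priors", seed = seed)
}

#' Regularization-weight grid at fixed prior percentages
#'
#' Scores the semi-supervised method over a `gamma1 x gamma2` grid with
#' fixed must-link and cannot-link percentages (defaults 5% and 5%),
#' averaging over `runs` constraint samples and initializations per cell.
#'
#' @inheritParams prior_sweep
#' @param gamma1_values,gamma2_values Nonnegative weight grids.
#' @param pct_must,pct_cannot Prior fractions of the budgets.
#' @return An `sscd_sweep` tibble: one row per `(gamma1, gamma2)` cell.
#' @export
param_grid <- function(network, truth, k = NULL,
                       gamma1_values = c(0, 0.1, 1, 5, 10),
                       gamma2_values = c(0, 0.1, 1, 5, 10),
                       pct_must = 0.05, pct_cannot = 0.05,
                       runs = 50, seed = 1, ...) {
  truth <- as_partition(truth)
  k <- k %||% max(truth$community)
  grid <- tidyr::expand_grid(gamma1 = gamma1_values, gamma2 = gamma2_values)
  cells <- purrr::pmap(grid, function(gamma1, gamma2) {
    res <- purrr::map(seq_len(runs), function(r) {
      s <- derive_seed(seed, round(gamma1 * 1000), round(gamma2 * 1000), r)
      tryCatch({
        cs <- sample_constraints(truth, pct_must = pct_must, pct_cannot = pct_cannot,
                                 seed = derive_seed(s, "constraints"))
        fit <- sscd_fit(network, k = k, constraints = cs,
                        gamma1 = gamma1, gamma2 = gamma2, seed = s, ...)
        part <- hard_assign(fit)
        c(nmi = nmi(part, truth), purity = purity(part, truth))
      }, error = function(e) c(nmi = NA_real_, purity = NA_real_))
    })
    m <- do.call(rbind, res)
    tibble::tibble(nmi_mean = mean(m[, "nmi"], na.rm = TRUE),
                   nmi_var = stats::var(m[, "nmi"], na.rm = TRUE),
                   purity_mean = mean(m[, "purity"], na.rm = TRUE),
                   purity_var = stats::var(m[, "purity"], na.rm = TRUE),
                   runs = runs, failed = sum(is.na(m[, "nmi"])))
  })
  out <- dplyr::bind_cols(grid, dplyr::bind_rows(cells))
  structure(out, class = c("sscd_sweep", class(out)),
            sweep_type = "params", seed = seed,
            pct_must = pct_must, pct_cannot = pct_cannot)
}

#' Plot a sweep result
#'
#' Prior sweeps plot mean NMI against prior percentage per method;
#' parameter grids plot a `gamma1 x gamma2` NMI heat map.
#'
#' @param object An `sscd_sweep`.
#' @param metric `"nmi"` or `"purity"`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.sscd_sweep <- function(object, metric = c("nmi", "purity"), ...) {
  metric <- match.arg(metric)
  ycol <- paste0(metric, "_mean")
  if (identical(attr(object, "sweep_type"), "params")) {
    ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$gamma1),
                                         y = factor(.data$gamma2),
                                         fill = .data[[ycol]])) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "gamma1 (negative links)", y = "gamma2 (positive links)",
                    fill = metric) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$percentage,
                                         y = .data[[ycol]],
                                         colour = .data$method)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "prior percentage (% of budget)", y = paste("mean", metric)) +
      ggplot2::theme_minimal()
  }
}
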