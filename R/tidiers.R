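#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted hash model
#'
#' One row per feature domain: input dimensionality, code length and the
#' Frobenius norm of the learned coefficient block.
#'
#' @param x A `fed_hash_fit`.
#' @param ... Unused.
#' @return A tibble with columns `domain`, `d`, `bits`, `w_norm`.
#' @method tidy fed_hash_fit
#' @export
tidy.fed_hash_fit <- function(x, ...) {
  tibble::tibble(
    domain = x$domains,
    d = vapply(x$W, nrow, integer(1)),
    bits = vapply(x$W, ncol, integer(1)),
    w_norm = vapply(x$W, function(w) sqrt(sum(w * w)), numeric(1))
  )
}

#' Glance at a fitted hash model
#'
#' @param x A `fed_hash_fit`.
#' @param ... Unused.
#' @return One-row tibble: fit method, problem size, iterations, convergence
#'   flag and the initial/final objective.
#' @method glance fed_hash_fit
#' @export
glance.fed_hash_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_sites = x$n_sites,
    n_patients = x$n_patients,
    n_domains = length(x$domains),
    total_bits = sum(x$bits),
    iterations = x$iterations,
    converged = x$converged,
    objective_initial = x$trace[1],
    objective_final = x$trace[length(x$trace)]
  )
}

#' Plot the optimization trace of a hash-model fit
#'
#' @param object A `fed_hash_fit`.
#' @param ... Unused.
#' @return A ggplot of the objective value per block-coordinate sweep.
#' @method autoplot fed_hash_fit
#' @export
autoplot.fed_hash_fit <- function(object, ...) {
  df <- tibble::tibble(sweep = seq_along(object$trace) - 1L, objective = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$objective)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "block-coordinate sweep", y = "objective",
                  title = sprintf("%s fit, %d site(s)", object$method, object$n_sites)) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validated metric report
#'
#' Boxplots of per-repeat AUC by neighbourhood size, faceted by system /
#' code mode (and arm, for imbalance experiments).
#'
#' @param object A `fedsim_metrics` tibble from [run_experiment()].
#' @param metric Which metric column to plot (default `"auc"`).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fedsim_metrics
#' @export
autoplot.fedsim_metrics <- function(object, metric = "auc", ...) {
  facet <- if ("arm" %in% names(object)) {
    ggplot2::facet_grid(arm ~ system + code_mode)
  } else {
    ggplot2::facet_wrap(~ system + code_mode)
  }
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$kappa), y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    facet +
    ggplot2::labs(x = expression(kappa), y = metric) +
    ggplot2::theme_minimal()
}
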