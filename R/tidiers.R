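#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Gaussian-mixture fit
#'
#' @param x A [fit_gmm()] result.
#' @param ... Unused.
#' @return One row per component: `component`, `weight`, `mean`, `sd`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble::tibble(component = seq_len(x$k), weight = x$weight,
                 mean = x$mean, sd = x$sd)
}

#' @rdname tidy.gmm_fit
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, loglik = x$loglik, bic = x$bic, n = x$n,
                 converged = x$converged, iterations = x$iterations)
}

#' Tidy a mutual-information estimate
#'
#' @param x A [mi_shrinkage()] result.
#' @param ... Unused.
#' @return One row per contingency cell: `bin_x`, `bin_y`, `count`.
#' @export
tidy.mi_estimate <- function(x, ...) {
  df <- as.data.frame(x$table, stringsAsFactors = FALSE)
  tibble::tibble(bin_x = as.integer(df[[1]]), bin_y = as.integer(df[[2]]),
                 count = df[[3]])
}

#' @rdname tidy.mi_estimate
#' @export
glance.mi_estimate <- function(x, ...) {
  tibble::tibble(mi_nats = x$value, lambda = x$lambda, n = x$n,
                 n_bins_x = length(x$edges_x) - 1,
                 n_bins_y = length(x$edges_y) - 1)
}

#' Tidy an equilibrium set
#'
#' @param x An [equilibria()] result.
#' @param ... Unused.
#' @export
tidy.equilibrium_set <- function(x, ...) {
  tibble::tibble(level = x$level, stable = x$stable)
}

#' @rdname tidy.equilibrium_set
#' @export
glance.equilibrium_set <- function(x, ...) {
  tibble::tibble(classification = attr(x, "classification"),
                 n_equilibria = nrow(x), n_stable = sum(x$stable),
                 degenerate = attr(x, "degenerate"))
}

#' Plot a risk map
#'
#' Tiles the `(alpha, gamma)` grid by wild-type classification and hatches
#' (points) the cells at risk of a qualitative change under the reporter
#' design.
#'
#' @param object A [risk_map()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$gamma)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$class_wt)) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$at_risk),
                        shape = 4, size = 1) +
    ggplot2::scale_fill_manual(values = c(bistable = "#74add1",
                                          monostable = "#fee090")) +
    ggplot2::labs(fill = "wild type",
                  title = sprintf("At-risk region, gamma factor %.3g",
                                  attr(object, "gamma_factor")))
}

#' Plot the fold (saddle-node) curves
#'
#' @param curves Output of [bifurcation_curves()].
#' @return A ggplot of the two fold branches and the cusp in the
#'   `(alpha, gamma)` plane.
#' @export
plot_bifurcation_curves <- function(curves) {
  cusp <- attr(curves, "cusp")
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$alpha, y = .data$gamma,
                                            linetype = .data$branch)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = expression(alpha), y = expression(gamma))
  if (!is.null(cusp)) {
    p <- p + ggplot2::annotate("point", x = cusp["alpha"], y = cusp["gamma"])
  }
  p
}

#' Plot a mixture fit over the data
#'
#' @param object A [fit_gmm()] result.
#' @param values The values the fit was computed on.
#' @param ... Unused.
#' @return A ggplot: histogram plus weighted component densities.
#' @export
autoplot.gmm_fit <- function(object, values, ...) {
  grid <- seq(min(values), max(values), length.out = 400)
  comp <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(component = factor(j), x = grid,
                   density = object$weight[j] *
                     stats::dnorm(grid, object$mean[j], object$sd[j]))
  })
  ggplot2::ggplot(tibble::tibble(values = values),
                  ggplot2::aes(x = .data$values)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80") +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(x = .data$x, y = .data$density,
                                    colour = .data$component))
}

#' Plot per-day mutual information from a flow report
#'
#' @param report A `flow_report` from [run_flow_analysis()].
#' @return A ggplot of MI (nats) against day, one line per condition.
#' @export
plot_mi_timecourse <- function(report) {
  stopifnot(inherits(report, "flow_report"))
  ggplot2::ggplot(report$per_group,
                  ggplot2::aes(x = .data$day, y = .data$mi_nats,
                               colour = .data$condition)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(y = "mutual information (nats)")
}
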