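#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a rate/yield spectrum
#'
#' Scatter of growth rate against biomass yield, one point per flux mode,
#' with the Pareto-optimal modes highlighted.
#'
#' @param object an `efcm_spectrum` from [rate_yield_spectrum()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot efcm_spectrum
#' @export
autoplot.efcm_spectrum <- function(object, ...) {
  front <- pareto_front(object)
  ggplot2::ggplot(object[object$status == "ok", ],
                  ggplot2::aes(x = .data$yield_g_per_cmol, y = .data$mu)) +
    ggplot2::geom_point(colour = "grey40") +
    ggplot2::geom_point(data = front, colour = "firebrick", shape = 15,
                        size = 2.5) +
    ggplot2::geom_line(data = front, colour = "firebrick",
                       linetype = "dashed") +
    ggplot2::labs(x = "biomass yield (g/C-mol)",
                  y = expression(mu ~ (h^{-1})),
                  title = "Rate/yield spectrum (Pareto front in red)") +
    ggplot2::theme_minimal()
}

#' Plot a Monod scan
#'
#' With an oxygen grid this is a heatmap of the best growth rate over the
#' glucose x oxygen plane; with a glucose-only scan it is the classic Monod
#' curve (log-scaled glucose axis).
#'
#' @param object an `efcm_monod` from [monod_scan()].
#' @param fill which column to map to fill in the 2-D case (default `mu`).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot efcm_monod
#' @export
autoplot.efcm_monod <- function(object, fill = "mu", ...) {
  if (all(is.na(object$oxygen_mM))) {
    return(
      ggplot2::ggplot(object, ggplot2::aes(x = .data$glucose_mM,
                                           y = .data$mu)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "glucose (mM)", y = expression(mu ~ (h^{-1})),
                      title = "Monod curve of the best strategy") +
        ggplot2::theme_minimal()
    )
  }
  ggplot2::ggplot(object, ggplot2::aes(x = .data$glucose_mM,
                                       y = .data$oxygen_mM,
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "glucose (mM)", y = "oxygen (mM)", fill = fill,
                  title = "Monod surface") +
    ggplot2::theme_minimal()
}

#' Protein-investment breakdown of an ECM solution
#'
#' Bar chart of each active reaction's share of the total enzyme cost.
#'
#' @param solution an `ecm_solution`.
#' @return a ggplot object.
#' @export
plot_cost_breakdown <- function(solution) {
  d <- solution$reactions
  d$share <- d$cost_mg_per_l / sum(d$cost_mg_per_l)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$reaction_id,
                                                     -.data$share),
                                  y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of enzyme cost",
                  title = sprintf("Protein investment (E_met = %.4g mg/l)",
                                  solution$E_met)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
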