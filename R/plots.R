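#' Plot a dynamic trajectory
#'
#' Biomass (top panel, log-friendly) and substrate pools over time.
#'
#' @param object A `pa_trajectory`.
#' @param pools Optional character vector restricting which pooled exchanges
#'   are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_trajectory
#' @export
autoplot.pa_trajectory <- function(object, pools = NULL, ...) {
  pl <- object$pools
  if (!is.null(pools)) pl <- pl[pl$exchange %in% pools, ]
  long <- bind_rows(
    tibble(time = object$states$time, series = "biomass",
           value = object$states$biomass),
    tibble(time = pl$time, series = pl$exchange, value = pl$amount)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (h)", y = "amount (units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a growth gradient surface
#'
#' @param object A `pa_gradient` from [gradient_scan()].
#' @param ... Unused.
#' @return A ggplot tile map of the growth optimum over the two uptake axes.
#' @method autoplot pa_gradient
#' @export
autoplot.pa_gradient <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$bound1, .data$bound2,
                               fill = .data$mu)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = expression(mu ~ (h^-1))) +
    ggplot2::labs(x = attr(object, "source1"), y = attr(object, "source2")) +
    ggplot2::theme_minimal()
}

#' Plot a supplement screen
#'
#' Ranked bar chart of per-supplement growth optima, coloured by class when
#' [classify_supplements()] has been applied.
#'
#' @param object A `pa_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pa_screen
#' @export
autoplot.pa_screen <- function(object, ...) {
  df <- as_tibble(object)
  df$exchange <- stats::reorder(df$exchange, df$mu)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$exchange, .data$mu))
  p <- if ("class" %in% names(df)) {
    p + ggplot2::geom_col(ggplot2::aes(fill = .data$class))
  } else {
    p + ggplot2::geom_col()
  }
  p + ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(mu ~ (h^-1))) +
    ggplot2::theme_minimal()
}

#' Plot substrate depletion curves
#'
#' @param trajectory A `pa_trajectory`.
#' @param targets Exchange ids to draw (default: all pooled).
#' @return A ggplot object.
#' @export
plot_degradation <- function(trajectory, targets = NULL) {
  autoplot(trajectory, pools = targets) +
    ggplot2::labs(y = "amount remaining (units)")
}
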