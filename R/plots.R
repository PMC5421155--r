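#' Plot a potential-yield response surface
#'
#' Mean potential yield against sowing/transplanting date, one line per
#' maturity class, faceted by crop -- the shape on which sequence selection
#' operates. Error ribbons show +/- one inter-annual standard deviation.
#'
#' @param surface A `yield_surface` tibble.
#' @return A ggplot object.
#' @export
plot_yield_surface <- function(surface) {
  smry <- summarize_surface(surface) |>
    dplyr::mutate(sd = .data$mean_yp_t_ha * .data$cv_pct / 100)
  ggplot2::ggplot(smry, ggplot2::aes(.data$sowing_doy, .data$mean_yp_t_ha,
                                     colour = .data$variety,
                                     fill = .data$variety)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_yp_t_ha - .data$sd,
                                      ymax = .data$mean_yp_t_ha + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$crop)) +
    ggplot2::labs(x = "sowing / transplanting date (DOY)",
                  y = "mean potential yield (t ha⁻¹)",
                  colour = "maturity class", fill = "maturity class") +
    ggplot2::theme_minimal()
}

#' @rdname plot_yield_surface
#' @param object A `yield_surface` tibble.
#' @param ... Unused.
#' @method autoplot yield_surface
#' @export
autoplot.yield_surface <- function(object, ...) {
  plot_yield_surface(object)
}

#' Plot the yield-gap decomposition
#'
#' Stacked management (CSYgM) and arrangement (CSYgA) gap components per
#' location or system, below the line marking CSYp*.
#'
#' @param gaps Tibble with a `location` (or `system`) column and gap columns
#'   `csygm<suffix>`, `csyga<suffix>`.
#' @param suffix Unit-basis suffix of the gap columns.
#' @return A ggplot object.
#' @export
plot_gap_decomposition <- function(gaps, suffix = "_t_ha") {
  gm <- paste0("csygm", suffix); ga <- paste0("csyga", suffix)
  id <- if ("system" %in% names(gaps)) "system" else "location"
  long <- gaps |>
    dplyr::select(dplyr::all_of(c(id, gm, ga))) |>
    tidyr::pivot_longer(-dplyr::all_of(id), names_to = "component",
                        values_to = "gap") |>
    dplyr::mutate(component = ifelse(startsWith(.data$component, "csygm"),
                                     "management (CSYgM)",
                                     "arrangement (CSYgA)"))
  unit <- if (suffix == "_gj_ha") "GJ ha⁻¹ yr⁻¹" else
    "t ha⁻¹ yr⁻¹"
  ggplot2::ggplot(long, ggplot2::aes(.data[[id]], .data$gap,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = paste0("yield gap (", unit, ")"),
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
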