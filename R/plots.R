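#' Plot a simulated trajectory
#'
#' Weekly flux rates (GPP, ecosystem respiration, NEE) and leaf area index.
#'
#' @param object A `fen_sim` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fen_sim <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(t = dplyr::row_number()) |>
    dplyr::select(t, gpp, reco, nee, lai) |>
    tidyr::pivot_longer(-t, names_to = "variable")
  ggplot2::ggplot(df, ggplot2::aes(t, value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "week", y = NULL)
}

#' Plot an annual ensemble summary with its 95% band
#'
#' @param annual Tibble from [annual_summary()] or [relative_change()].
#' @param variables Variables to show.
#' @return A ggplot object.
#' @export
plot_annual_summary <- function(annual, variables = c("gpp", "rh", "lai")) {
  df <- dplyr::filter(annual, variable %in% variables)
  ggplot2::ggplot(df, ggplot2::aes(year, median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lower, ymax = upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "median and 95% interval")
}

#' Plot posterior marginal densities of an ensemble
#'
#' @param ensemble A `fen_ensemble` tibble.
#' @param parameters Parameter names to show.
#' @param truth Optional named truth vector to overlay.
#' @return A ggplot object.
#' @export
plot_ensemble_density <- function(ensemble,
                                  parameters = c("f_auto", "c_eff", "theta",
                                                 "r_som"),
                                  truth = NULL) {
  df <- tidyr::pivot_longer(ensemble[, parameters], dplyr::everything(),
                            names_to = "parameter")
  p <- ggplot2::ggplot(df, ggplot2::aes(value)) +
    ggplot2::geom_density(fill = "grey80") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, y = "posterior density")
  if (!is.null(truth)) {
    tv <- tibble::tibble(parameter = parameters,
                         value = as.numeric(truth[parameters]))
    p <- p + ggplot2::geom_vline(data = tv,
                                 ggplot2::aes(xintercept = value),
                                 linetype = 2)
  }
  p
}
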