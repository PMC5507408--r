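#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a regression_stats object
#'
#' One row with the slope, intercept (um), R2, RMSE (um), RMSE%, MaxError
#' (um), Lin's CC and point counts.
#'
#' @param x A `regression_stats` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy regression_stats
#' @export
tidy.regression_stats <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r2 = x$r2,
                 rmse = x$rmse, rmse_pct = x$rmse_pct,
                 max_error = x$max_error, cc = x$cc,
                 n_points = x$n_points, n_removed = x$n_removed)
}

#' @rdname tidy.regression_stats
#' @method glance regression_stats
#' @export
glance.regression_stats <- function(x, ...) tidy(x, ...)

#' Tidy a back-calculation result
#'
#' @param x A `back_calc` object.
#' @param ... Unused.
#' @return A one-row tibble with `e_backcalc` (GPa), `scale`, `e_ref`,
#'   `residual_norm` (N) and `n`.
#' @method tidy back_calc
#' @export
tidy.back_calc <- function(x, ...) {
  tibble::tibble(e_backcalc = x$e_backcalc, scale = x$scale, e_ref = x$e_ref,
                 residual_norm = x$residual_norm, n = x$n)
}

#' @rdname tidy.back_calc
#' @method glance back_calc
#' @export
glance.back_calc <- function(x, ...) tidy(x, ...)

#' Scatter plot of predicted versus measured displacements
#'
#' One panel per displacement direction with the identity line; the
#' conventional way of presenting microFE-vs-DVC local displacement
#' validation.
#'
#' @param object A `comparison_table` from [select_comparison_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comparison_table
#' @export
autoplot.comparison_table <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), cols = dplyr::starts_with("u_"),
    names_to = c("source", "direction"), names_pattern = "u_(dvc|fe)_(.)",
    values_to = "u")
  wide <- tidyr::pivot_wider(long, names_from = "source", values_from = "u")
  wide$direction <- toupper(wide$direction)
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$dvc, y = .data$fe)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~direction, scales = "free") +
    ggplot2::labs(x = "measured displacement (DVC) [um]",
                  y = "predicted displacement (microFE) [um]") +
    ggplot2::theme_bw()
}

#' Histogram of principal strains with yield limits
#'
#' Frequency plot of the first (tensile) and third (compressive) principal
#' element strains, with the yield limits marked; elements beyond the limits
#' are where a linear-elastic model is no longer trustworthy.
#'
#' @param strains A `strain_field` from [element_strains()].
#' @param crit A [yield_criteria()].
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_strain_distribution <- function(strains, crit = yield_criteria(),
                                     bins = 60) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(strains)[, c("element", "p1", "p3")],
    cols = c("p1", "p3"), names_to = "principal", values_to = "strain")
  df$strain <- df$strain * 1e6
  df$principal <- factor(df$principal, c("p1", "p3"),
                         c("first (tension)", "third (compression)"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strain, fill = .data$principal)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = c(crit$eps_p1y, crit$eps_p3y),
                        linetype = 2) +
    ggplot2::labs(x = "principal strain [microstrain]", y = "elements",
                  fill = NULL) +
    ggplot2::theme_bw()
}
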