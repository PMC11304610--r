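#' Plot methods
#'
#' `autoplot()` methods for the curve and summary classes, in ggplot2.
#'
#' @param object the object to plot.
#' @param ... unused.
#' @return A ggplot.
#' @name plots
NULL

#' @rdname plots
#' @export
autoplot.stress_strain_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$strain, y = .data$stress_mpa)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Engineering strain [%]", y = "Engineering stress [MPa]",
                  title = attr(object, "model_id")) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.averaged_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$strain, y = .data$stress_mpa)) +
    ggplot2::geom_line(colour = "#636363") +
    ggplot2::labs(x = "Engineering strain [%]", y = "Engineering stress [MPa]",
                  subtitle = "averaged, filtered") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @export
autoplot.e_inc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = 100 * .data$strain, y = .data$e_inc_mpa)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::geom_line(colour = "#d95f02") +
    ggplot2::labs(x = "Engineering strain [%]",
                  y = expression(E[inc] ~ "[MPa]")) +
    ggplot2::theme_minimal()
}

#' Max stress vs strain scatter of models and references
#'
#' The summary scatter comparing printed/synthetic model batches with the
#' aortic-tissue literature values (mean +/- sd error bars on both axes).
#'
#' @param summaries a `tensile_summary` tibble.
#' @param references reference tibble, default [aorta_reference_table()].
#' @return A ggplot.
#' @export
plot_stress_strain_scatter <- function(summaries,
                                       references = aorta_reference_table()) {
  mod <- tibble::tibble(label = summaries$model_id,
                        stress = summaries$max_stress_mpa,
                        stress_sd = summaries$max_stress_sd,
                        strain = summaries$strain_at_max_pct,
                        strain_sd = summaries$strain_at_max_sd,
                        group = "printed model")
  ref <- tibble::tibble(label = references$label,
                        stress = references$max_stress_mpa,
                        stress_sd = references$max_stress_sd,
                        strain = references$strain_at_max_pct,
                        strain_sd = references$strain_at_max_sd,
                        group = "aortic tissue")
  dat <- dplyr::bind_rows(mod, ref)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$strain, y = .data$stress,
                                    colour = .data$group, shape = .data$group)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$stress - .data$stress_sd,
                                        ymax = .data$stress + .data$stress_sd),
                           width = 0, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$strain - .data$strain_sd,
                                         xmax = .data$strain + .data$strain_sd),
                            height = 0, alpha = 0.5, na.rm = TRUE) +
    ggplot2::geom_point(size = 2.5, na.rm = TRUE) +
    ggplot2::labs(x = "Strain at max stress [%]", y = "Max stress [MPa]",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}

#' Broom-style tidiers
#'
#' `tidy()` turns test and summary objects into tibbles; `glance()` gives a
#' one-row model-level view of the Welch test.
#'
#' @param x a `welch_one_sided` object or `tensile_summary` tibble.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.welch_one_sided <- function(x, ...) {
  tibble::tibble(estimate = x$mean1 - x$mean2, statistic = x$t,
                 parameter = x$df, p.value = x$p,
                 alternative = x$direction, reject = x$reject)
}

#' @rdname tidy.welch_one_sided
#' @export
glance.welch_one_sided <- function(x, ...) {
  tibble::tibble(statistic = x$t, df = x$df, p.value = x$p,
                 alpha = x$alpha, reject = x$reject)
}

#' @rdname tidy.welch_one_sided
#' @export
tidy.tensile_summary <- function(x, ...) {
  tibble::as_tibble(x)
}
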