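#' Plot a damage spectrum as per-category yield bars
#'
#' @param spectrum Damage-spectrum tibble (one or more rows); bars are
#'   grouped by quality label and faceted by oxygen level when several
#'   levels are present.
#' @param log_scale Use a log10 yield axis (default TRUE; category yields
#'   span four orders of magnitude).
#' @return A ggplot object.
#' @export
plot_damage_spectrum <- function(spectrum, log_scale = TRUE) {
  long <- spectrum |>
    tidyr::pivot_longer(dplyr::all_of(damage_categories()),
                        names_to = "category", values_to = "yield") |>
    dplyr::mutate(category = factor(.data$category,
                                    levels = damage_categories()))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$category,
                                          y = .data$yield,
                                          fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "damage category", y = "yield (per Gy per Gbp)",
                  fill = "quality")
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  if (length(unique(long$oxygen_percent)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$oxygen_percent),
                                 labeller = ggplot2::label_both)
  }
  p
}

#' Plot hypoxia-reduction-factor curves
#'
#' @param curve Output of [hrf_curve()], or several such tibbles bound
#'   together with a `label` column.
#' @return A ggplot object (HRF vs oxygen percent, log oxygen axis).
#' @export
plot_hrf_curve <- function(curve) {
  aes <- if ("label" %in% names(curve)) {
    ggplot2::aes(x = .data$o2_percent, y = .data$hrf, colour = .data$label)
  } else {
    ggplot2::aes(x = .data$o2_percent, y = .data$hrf)
  }
  ggplot2::ggplot(curve, aes) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "oxygen (%O2)", y = "hypoxia reduction factor",
                  colour = "quality")
}

#' Plot a secondary-electron fluence spectrum
#'
#' Line spectra are drawn as vertical segments; density spectra as a curve
#' on log-log axes.
#'
#' @param fluence A fluence-spectrum tibble.
#' @return A ggplot object.
#' @export
plot_fluence_spectrum <- function(fluence) {
  lab <- attr(fluence, "label") %||% ""
  if (is_line_spectrum(fluence)) {
    ggplot2::ggplot(fluence, ggplot2::aes(x = .data$energy_eV,
                                          xend = .data$energy_eV,
                                          y = 0, yend = .data$fluence)) +
      ggplot2::geom_segment() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "electron energy (eV)", y = "relative fluence",
                    title = lab)
  } else {
    ggplot2::ggplot(fluence, ggplot2::aes(x = .data$energy_eV,
                                          y = .data$fluence)) +
      ggplot2::geom_line() +
      ggplot2::scale_x_log10() +
      ggplot2::scale_y_log10() +
      ggplot2::labs(x = "electron energy (eV)",
                    y = "fluence density (per eV, relative)", title = lab)
  }
}

#' @describeIn calibrate_oxygen Autoplot: fitted oxygen-scaling curves with
#'   the calibration points overlaid (relative to the aerobic level).
#' @param object An `oxygen_fit`.
#' @param ... Unused.
#' @export
autoplot.oxygen_fit <- function(object, ...) {
  o2 <- 10^seq(log10(0.01), log10(21), length.out = 200)
  curves <- purrr::map_dfr(damage_categories(), function(cat) {
    tibble(category = cat, o2_percent = o2,
           scale = oxygen_scale(o2, cat, object$response) /
             oxygen_scale(21, cat, object$response))
  })
  curves$category <- factor(curves$category, levels = damage_categories())
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$o2_percent,
                                            y = .data$scale)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "oxygen (%O2)", y = "yield relative to 21% O2",
                  title = object$label)
  if (!is.null(object$fitted_rel) && length(object$oxygen_percent) > 0) {
    pts <- tidyr::expand_grid(o2_percent = object$oxygen_percent,
                              category = damage_categories())
    pts$scale <- mapply(function(o, cc) object$fitted_rel[
      match(o, object$oxygen_percent), cc
    ], pts$o2_percent, pts$category)
    pts$category <- factor(pts$category, levels = damage_categories())
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$o2_percent, y = .data$scale)
    )
  }
  p
}

#' @describeIn calibrate_induction Autoplot: calibrated vs target yields per
#'   category on a log-log identity plot.
#' @param object An `induction_fit`.
#' @param ... Unused.
#' @export
autoplot.induction_fit <- function(object, ...) {
  if (is.null(object$residuals)) {
    abort("this induction_fit carries no residuals to plot")
  }
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$target, y = .data$fitted,
                               label = .data$column)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "target yield (per Gy per Gbp)",
                  y = "calibrated yield (per Gy per Gbp)")
}
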