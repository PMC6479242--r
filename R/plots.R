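#' Plot mean concentration--time profiles of a study
#'
#' Arithmetic mean concentration by treatment with +/- SD ribbons, the
#' standard way crossover PK profiles are displayed.
#'
#' @param object A [pk_study()].
#' @param ribbon Draw the +/- SD ribbon (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_study <- function(object, ribbon = TRUE, ...) {
  d <- dplyr::summarise(
    dplyr::group_by(object$conc, .data$treatment, .data$time_h),
    mean_conc = mean(.data$conc_ng_ml),
    sd_conc = sd(.data$conc_ng_ml),
    .groups = "drop"
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$mean_conc,
                                       colour = .data$treatment)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Time post-dose (h)",
                  y = "Mean plasma concentration (ng/mL)",
                  colour = "Treatment") +
    ggplot2::theme_minimal()
  if (ribbon) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(0, .data$mean_conc - .data$sd_conc),
                   ymax = .data$mean_conc + .data$sd_conc,
                   fill = .data$treatment),
      alpha = 0.15, colour = NA)
  }
  p
}

#' Plot a one-compartment fit against the observed mean profile
#'
#' @param object A `pk_one_cpt_fit`.
#' @param n_grid Number of grid points for the fitted curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_one_cpt_fit <- function(object, n_grid = 400, ...) {
  grid <- seq(min(object$data$time_h), max(object$data$time_h),
              length.out = n_grid)
  curve <- tibble::tibble(
    time_h = grid,
    conc_ng_ml = one_cpt_conc(object$params, object$dose_mg, grid)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = "Time post-dose (h)",
                  y = "Plasma concentration (ng/mL)",
                  title = sprintf("One-compartment lag fit, %g mg",
                                  object$dose_mg)) +
    ggplot2::theme_minimal()
}

#' Plot a multiple-dose simulation
#'
#' @param object A `pk_sim`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pk_sim <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = seq(0, by = object$tau_h,
                                         length.out = object$n_doses),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  title = sprintf("%d x %g mg every %g h",
                                  object$n_doses, object$dose_mg,
                                  object$tau_h)) +
    ggplot2::theme_minimal()
}
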