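# ggplot2 visualisations.

#' Plot a lambda-model fit
#'
#' DSRT against mean stretch speed, outliers highlighted, with the final
#' regression line. The intercept of the line is the TSRT biomarker.
#'
#' @param object A `lambda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lambda_fit <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_speed, y = .data$dsrt,
                                        colour = .data$outlier)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "#2166ac",
                                            `TRUE` = "#b2182b")) +
    ggplot2::labs(x = "mean stretch speed (deg/s)", y = "DSRT (deg)",
                  colour = "excluded") +
    ggplot2::theme_minimal()
  if (!object$fallback_used && is.finite(object$slope)) {
    p <- p + ggplot2::geom_abline(slope = object$slope,
                                  intercept = object$intercept_tsrt,
                                  linetype = "dashed")
  }
  p
}

#' Plot leave-one-out evaluation scores against MAS labels
#'
#' One panel per calibration method; the dotted line is identity, the solid
#' line the fitted score-versus-label regression.
#'
#' @param object A `spastr_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spastr_eval <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$label, y = .data$score)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~method) +
    ggplot2::labs(x = "clinical MAS (numeric)",
                  y = "evaluation score") +
    ggplot2::theme_minimal()
}

#' Plot actual against reconstructed kinematics of one stretch
#'
#' Three panels (angle, speed, acceleration) comparing the measured curves
#' with the scaled constant-jerk reconstruction.
#'
#' @param object A `kin_recon` from [reconstruct_kinematics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kin_recon <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::mutate(object$actual, time = object$time, source = "actual"),
    dplyr::mutate(object$recon, time = object$time, source = "reconstructed")
  ) |>
    tidyr::pivot_longer(c("angle", "speed", "acc"),
                        names_to = "curve", values_to = "value") |>
    dplyr::mutate(curve = factor(.data$curve,
                                 levels = c("angle", "speed", "acc")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     linetype = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~curve, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time from movement onset (s)", y = NULL) +
    ggplot2::theme_minimal()
}
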