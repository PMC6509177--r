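# Broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a lambda-model fit
#'
#' @param x A `lambda_fit`.
#' @param ... Unused.
#' @return One row per DSRT point with its outlier flag.
#' @export
tidy.lambda_fit <- function(x, ...) {
  pts <- tibble::as_tibble(x$points)
  pts$outlier <- if (length(x$outlier_mask) == nrow(pts)) x$outlier_mask else
    rep(FALSE, nrow(pts))
  pts
}

#' One-row summary of a lambda-model fit
#'
#' @param x A `lambda_fit`.
#' @param ... Unused.
#' @return A tibble with `tsrt`, `slope`, `r2`, `n_points`, `fallback_used`.
#' @export
glance.lambda_fit <- function(x, ...) {
  tibble::tibble(
    tsrt = x$intercept_tsrt,
    slope = x$slope,
    r2 = x$r2,
    n_points = x$n_points,
    fallback_used = x$fallback_used
  )
}

#' Tidy a fitted SVR model
#'
#' @param x A `spastr_svr`.
#' @param ... Unused.
#' @return One row per training point with its dual coefficient and
#'   support-vector status.
#' @export
tidy.spastr_svr <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$dual_coeffs),
    dual_coeff = x$dual_coeffs,
    support_vector = abs(x$dual_coeffs) > x$config$penalty_c * 1e-6
  )
}

#' One-row summary of a fitted SVR model
#'
#' @param x A `spastr_svr`.
#' @param ... Unused.
#' @export
glance.spastr_svr <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_support = sum(abs(x$dual_coeffs) > x$config$penalty_c * 1e-6),
    bias = x$bias,
    objective = x$objective,
    penalty_c = x$config$penalty_c,
    epsilon = x$config$epsilon,
    sigma = x$kernel$sigma
  )
}

#' Tidy an evaluation result
#'
#' @param x A `spastr_eval`.
#' @param ... Unused.
#' @return The per-subject score table (subject, label, method, score).
#' @export
tidy.spastr_eval <- function(x, ...) {
  x$scores
}

#' One-row summary of an evaluation result
#'
#' @param x A `spastr_eval`.
#' @param ... Unused.
#' @return A one-row tibble with one `mse_<method>` column per method and the
#'   number of scored subjects.
#' @export
glance.spastr_eval <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$mse[, c("method", "mse")],
                             names_from = "method", values_from = "mse",
                             names_prefix = "mse_")
  wide$n <- max(x$mse$n)
  wide
}

#' Tidy kinematic biomarkers
#'
#' @param x A `kinematic_biomarkers`.
#' @param ... Unused.
#' @return The per-trial correlation/MDF table.
#' @export
tidy.kinematic_biomarkers <- function(x, ...) {
  x$per_trial
}

#' One-row summary of kinematic biomarkers
#'
#' @param x A `kinematic_biomarkers`.
#' @param ... Unused.
#' @export
glance.kinematic_biomarkers <- function(x, ...) {
  tibble::tibble(
    corr_angle = x$corr_angle,
    corr_speed = x$corr_speed,
    corr_acc = x$corr_acc,
    mdf_acc = x$mdf_acc,
    n_trials_used = x$n_trials_used
  )
}
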