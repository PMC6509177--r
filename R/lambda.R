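# Lambda model: per-trial dynamic stretch reflex thresholds (DSRT), the
# per-subject DSRT-vs-velocity regression with 95% prediction-interval
# outlier exclusion, and the tonic stretch reflex threshold (TSRT) biomarker
# with the 120-degree healthy fallback.

#' Dynamic stretch reflex threshold of one trial
#'
#' The DSRT is the joint angle traversed from movement onset to the moment
#' the EMG burst is evoked, obtained as the trapezoidal integral of the
#' angular speed from `move_on` to the EMG onset mapped onto the 100 Hz speed
#' time base (nearest sample).
#'
#' @param pt A `preprocessed_trial` that passed QC and has movement bounds.
#' @return The traversed angle in degrees, or `NA` when the trial has no EMG
#'   onset (or the onset precedes movement onset, which raises a warning).
#' @export
compute_dsrt <- function(pt) {
  stopifnot(inherits(pt, "preprocessed_trial"))
  if (is.na(pt$move_on) || is.na(pt$emg_onset)) return(NA_real_)
  t_on <- (pt$emg_onset - 1) / pt$fs_emg
  i_g <- round(t_on * pt$fs_gyro) + 1L
  if (i_g < pt$move_on) {
    warn(paste0("EMG onset precedes movement onset in trial ", pt$trial_id,
                "; DSRT undefined"))
    return(NA_real_)
  }
  i_g <- min(i_g, pt$move_off)
  if (i_g == pt$move_on) return(0)
  idx <- pt$move_on:i_g
  trapz_int((idx - 1) / pt$fs_gyro, pt$speed[idx])
}

new_lambda_fit <- function(slope, intercept_tsrt, r2, n_points,
                           outlier_mask, fallback_used, points, level = 0.95) {
  structure(
    list(slope = slope, intercept_tsrt = intercept_tsrt, r2 = r2,
         n_points = n_points, outlier_mask = outlier_mask,
         fallback_used = fallback_used, points = points, level = level),
    class = "lambda_fit"
  )
}

#' Fit the lambda model to DSRT-velocity points
#'
#' Ordinary least-squares regression of DSRT (deg) on mean stretch speed
#' (deg/s), with one-shot outlier exclusion: points falling outside the
#' `level` (default 95%) prediction interval of the initial fit are flagged
#' and the line is recomputed once on the retained points. The intercept of
#' the final line is the tonic stretch reflex threshold (TSRT), the DSRT
#' extrapolated to zero stretch velocity. With exactly two points the
#' interpolating line is returned and no exclusion is attempted.
#'
#' @param points A tibble of DSRT points with columns `mean_speed` (> 0) and
#'   `dsrt` (deg); a `trial_id` column is carried through when present.
#' @param level Prediction-interval level for outlier flagging.
#' @return A `lambda_fit` object: `slope`, `intercept_tsrt`, `r2` (of the
#'   final fit), `n_points` (retained), `outlier_mask`, `fallback_used =
#'   FALSE`, and the input points.
#' @export
#' @examples
#' pts <- tibble::tibble(mean_speed = c(40, 80, 120),
#'                       dsrt = 46.765 - 0.277 * c(40, 80, 120))
#' fit_lambda(pts)$intercept_tsrt
fit_lambda <- function(points, level = 0.95) {
  stopifnot(is.data.frame(points),
            all(c("mean_speed", "dsrt") %in% names(points)))
  points <- tibble::as_tibble(points)
  n <- nrow(points)
  if (n < 2) {
    abort("need at least 2 DSRT points", class = "spastr_lambda_error")
  }
  if (stats::sd(points$mean_speed) == 0) {
    abort("ill-conditioned: zero variance in mean stretch speed",
          class = "spastr_lambda_error")
  }
  if (n == 2) {
    slope <- diff(points$dsrt) / diff(points$mean_speed)
    intercept <- points$dsrt[1] - slope * points$mean_speed[1]
    return(new_lambda_fit(slope, intercept, 1, 2L,
                          rep(FALSE, 2), FALSE, points, level))
  }
  fit0 <- lm(dsrt ~ mean_speed, data = points)
  # in-sample prediction intervals are exactly what the exclusion rule wants;
  # silence lm's note about future responses
  pi <- suppressWarnings(
    predict(fit0, interval = "prediction", level = level)
  )
  out <- unname(points$dsrt < pi[, "lwr"] | points$dsrt > pi[, "upr"])
  keep <- !out
  if (sum(keep) < 2) {
    # degenerate exclusion; keep the initial fit
    out <- rep(FALSE, n)
    keep <- !out
  }
  refit <- lm(dsrt ~ mean_speed, data = points[keep, ])
  # direct R^2 (summary.lm warns on noise-free fits)
  yk <- points$dsrt[keep]
  sst <- sum((yk - mean(yk))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(refit)^2) / sst else 1
  new_lambda_fit(unname(coef(refit)[2]), unname(coef(refit)[1]),
                 r2, sum(keep), out, FALSE, points, level)
}

#' TSRT biomarker of one session, with the healthy fallback
#'
#' Scans the QC-passed trials of a session for detected EMG onsets. Only when
#' the fraction of QC-passed trials with an onset strictly exceeds the
#' majority threshold (default 0.5) is the lambda regression fitted on the
#' per-trial DSRT points; otherwise the session is treated as showing no
#' typically evoked EMG and the TSRT is conformably set to the fallback value
#' of 120 degrees (the guaranteed minimum range of motion). A session with an
#' onset in exactly half of its trials therefore takes the fallback path.
#'
#' @param pts List of `preprocessed_trial` objects (one session).
#' @param majority Majority threshold on the onset fraction.
#' @param level Prediction-interval level passed to [fit_lambda()].
#' @param fallback_tsrt TSRT assigned on the fallback path (deg).
#' @return A `lambda_fit`; on the fallback path `fallback_used` is `TRUE`,
#'   `intercept_tsrt` equals `fallback_tsrt`, and `n_points` counts the
#'   trials that did have onsets.
#' @export
extract_tsrt <- function(pts, majority = 0.5, level = 0.95,
                         fallback_tsrt = 120) {
  qc <- purrr::keep(pts, function(p) isTRUE(p$qc_pass))
  if (length(qc) == 0) {
    abort("empty session: no QC-passed trials", class = "spastr_lambda_error")
  }
  has_onset <- purrr::map_lgl(qc, function(p) !is.na(p$emg_onset))
  frac <- mean(has_onset)
  dsrt <- purrr::map_dbl(qc, compute_dsrt)
  speed <- purrr::map_dbl(qc, function(p) p$mean_speed)
  ids <- purrr::map_chr(qc, function(p) p$trial_id)
  ok <- !is.na(dsrt) & is.finite(speed) & speed > 0
  points <- tibble::tibble(mean_speed = speed[ok], dsrt = dsrt[ok],
                           trial_id = ids[ok])
  if (frac <= majority || nrow(points) < 2) {
    return(new_lambda_fit(NA_real_, fallback_tsrt, NA_real_,
                          nrow(points), rep(FALSE, nrow(points)),
                          TRUE, points, level))
  }
  fit_lambda(points, level = level)
}

#' @export
print.lambda_fit <- function(x, ...) {
  if (x$fallback_used) {
    cat(sprintf(
      "<lambda_fit> fallback: TSRT = %.1f deg (%d trial(s) with onsets)\n",
      x$intercept_tsrt, x$n_points))
  } else {
    cat(sprintf(
      "<lambda_fit> TSRT = %.3f deg, slope = %.3f deg/(deg/s), R^2 = %.3f, %d/%d points retained\n",
      x$intercept_tsrt, x$slope, x$r2, x$n_points, nrow(x$points)))
  }
  invisible(x)
}
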