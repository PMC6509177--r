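# Kinematic model: constant-jerk reconstruction of the intended stretch
# motion and similarity/spectral biomarkers of the actual motion against it.

#' Split a stretch into accelerating and decelerating phases
#'
#' Divides the movement window at the moment of maximal angular speed:
#' `t1` runs from movement onset to the speed peak, `t2` from the peak to
#' movement offset. A plateau maximum is resolved to its earliest sample.
#'
#' @param speed Angular-speed series (deg/s).
#' @param move_on,move_off Movement bounds (sample indices into `speed`);
#'   default to the whole series.
#' @param fs Sampling rate in Hz.
#' @return List with `tmax_index` (sample index), `t1` and `t2` (s).
#' @export
split_phases <- function(speed, move_on = 1L, move_off = length(speed),
                         fs = 100) {
  stopifnot(move_on >= 1, move_off <= length(speed), move_on < move_off)
  tmax_index <- move_on - 1L + which.max(speed[move_on:move_off])
  list(
    tmax_index = tmax_index,
    t1 = (tmax_index - move_on) / fs,
    t2 = (move_off - tmax_index) / fs
  )
}

#' Constant-jerk reconstruction of the angular acceleration
#'
#' Builds the subtriangular (piecewise-linear, constant-jerk) intended
#' acceleration: an isoceles triangle rising to `acc1` over the accelerating
#' stage `t1`, then a negative isoceles triangle reaching `-acc2` over the
#' decelerating stage `t2`, with `acc2 = acc1 * t1 / t2` so the net velocity
#' change over the stretch is zero. The curve is sampled on the 100 Hz trial
#' grid; because the triangle vertices generally fall between samples, the
#' decelerating samples are rescaled once so the discrete trapezoidal
#' integral of the emitted series is exactly zero.
#'
#' @param t1,t2 Stage durations in seconds (> 0).
#' @param acc1 First-stage peak acceleration (deg/s^2), default 4000.
#' @param fs Sampling rate in Hz.
#' @return Numeric acceleration series on `seq(0, t1 + t2, by = 1/fs)`, with
#'   attributes `acc1`, `acc2` (= `acc1 * t1 / t2`), `t1`, `t2`, `fs`.
#' @export
#' @examples
#' a <- reconstruct_acceleration(0.4, 0.8)
#' attr(a, "acc2") # 2000
reconstruct_acceleration <- function(t1, t2, acc1 = 4000, fs = 100) {
  if (!is_scalar_num(t1) || !is_scalar_num(t2) || t1 <= 0 || t2 <= 0) {
    abort("stage durations t1 and t2 must be positive",
          class = "spastr_kinematic_error")
  }
  stopifnot(is_scalar_num(acc1), acc1 > 0)
  acc2 <- acc1 * t1 / t2
  n <- round((t1 + t2) * fs) + 1L
  tau <- (seq_len(n) - 1) / fs
  a <- numeric(n)
  in1 <- tau <= t1
  a[in1] <- acc1 * pmax(0, 1 - abs(2 * tau[in1] / t1 - 1))
  in2 <- !in1
  a[in2] <- -acc2 * pmax(0, 1 - abs(2 * (tau[in2] - t1) / t2 - 1))
  # exact discrete zero-net-velocity: scale the negative lobe
  pos <- pmax(a, 0)
  neg <- pmin(a, 0)
  area_pos <- trapz_int(tau, pos)
  area_neg <- -trapz_int(tau, neg)
  if (area_neg > 0) a <- pos + neg * (area_pos / area_neg)
  structure(a, acc1 = acc1, acc2 = acc2, t1 = t1, t2 = t2, fs = fs)
}

#' Reconstruct the intended kinematics of one stretch
#'
#' Integrates the constant-jerk acceleration twice (trapezoidal rule) to the
#' intended angle curve, scales it so its range of motion matches the actual
#' one, and differentiates the scaled angle once and twice (central finite
#' differences, one-sided at the ends) to obtain mutually consistent
#' reconstructed speed and acceleration curves. The actual angle curve is the
#' integral of the measured angular speed from movement onset (traversed
#' angle, starting at 0); the actual acceleration is its second derivative.
#' Pearson correlations between the actual and reconstructed angle, speed and
#' acceleration curves are attached.
#'
#' @param pt A QC-passed `preprocessed_trial` with movement bounds.
#' @param recon_acc Optional acceleration series from
#'   [reconstruct_acceleration()]; computed from the trial's phase split and
#'   `acc1` when omitted.
#' @param acc1 First-stage peak (deg/s^2) used when `recon_acc` is omitted.
#' @return A `kin_recon` object: phase split (`t1`, `t2`, `tmax_index`),
#'   `acc1`/`acc2`, `scale_factor`, a `time` vector, tibbles `actual` and
#'   `recon` (columns `angle`, `speed`, `acc`), and the named correlation
#'   vector `corr`.
#' @export
reconstruct_kinematics <- function(pt, recon_acc = NULL, acc1 = 4000) {
  stopifnot(inherits(pt, "preprocessed_trial"))
  if (is.na(pt$move_on)) {
    abort("trial has no movement bounds", class = "spastr_kinematic_error")
  }
  fs <- pt$fs_gyro
  sp <- split_phases(pt$speed, pt$move_on, pt$move_off, fs)
  if (sp$t1 <= 0 || sp$t2 <= 0) {
    abort("speed maximum at a movement bound; phases undefined",
          class = "spastr_kinematic_error")
  }
  if (is.null(recon_acc)) {
    recon_acc <- reconstruct_acceleration(sp$t1, sp$t2, acc1 = acc1, fs = fs)
  }
  idx <- pt$move_on:pt$move_off
  twin <- (idx - idx[1]) / fs
  ra <- as.numeric(recon_acc)
  if (length(ra) != length(idx)) {
    abort("reconstructed acceleration is not on the trial's stretch grid",
          class = "spastr_kinematic_error")
  }
  vel_u <- cumtrapz_int(twin, ra)
  ang_u <- cumtrapz_int(twin, vel_u)
  rom_u <- diff(range(ang_u))
  if (rom_u <= .Machine$double.eps) {
    abort("zero reconstructed range of motion", class = "spastr_kinematic_error")
  }
  actual_speed <- pt$speed[idx]
  actual_angle <- cumtrapz_int(twin, actual_speed)
  rom_a <- diff(range(actual_angle))
  scale_factor <- rom_a / rom_u

  recon_angle <- ang_u * scale_factor
  recon_speed <- pracma::gradient(recon_angle, 1 / fs)
  recon_acc_f <- pracma::gradient(recon_speed, 1 / fs)
  actual_acc <- pracma::gradient(actual_speed, 1 / fs)

  structure(
    list(
      trial_id = pt$trial_id,
      t1 = sp$t1, t2 = sp$t2, tmax_index = sp$tmax_index,
      acc1 = attr(recon_acc, "acc1") %||% acc1,
      acc2 = attr(recon_acc, "acc2") %||% NA_real_,
      scale_factor = scale_factor,
      time = twin,
      actual = tibble::tibble(angle = actual_angle, speed = actual_speed,
                              acc = actual_acc),
      recon = tibble::tibble(angle = recon_angle, speed = recon_speed,
                             acc = recon_acc_f),
      corr = c(
        angle = cor(actual_angle, recon_angle),
        speed = cor(actual_speed, recon_speed),
        acc = cor(actual_acc, recon_acc_f)
      )
    ),
    class = "kin_recon"
  )
}

#' Median frequency of a series
#'
#' Frequency at which the cumulative one-sided periodogram power (after mean
#' removal, DC excluded) first reaches half of the total power, with linear
#' interpolation between frequency bins.
#'
#' @param x Numeric series, length >= 32, non-zero variance.
#' @param fs Sampling rate in Hz.
#' @return Median frequency in Hz.
#' @export
#' @examples
#' t <- seq(0, 2, by = 0.01)
#' median_frequency(sin(2 * pi * 5 * t), fs = 100)
median_frequency <- function(x, fs = 100) {
  n <- length(x)
  if (n < 32) {
    abort("need at least 32 samples for a median-frequency estimate",
          class = "spastr_kinematic_error")
  }
  if (stats::var(x) == 0) {
    abort("zero-variance series has no median frequency",
          class = "spastr_kinematic_error")
  }
  x <- x - mean(x)
  p_all <- Mod(stats::fft(x))^2
  kmax <- floor(n / 2)
  p <- p_all[2:(kmax + 1L)]          # one-sided, DC excluded
  freqs <- (1:kmax) * fs / n
  cum <- cumsum(p)
  half <- cum[kmax] / 2
  j <- which(cum >= half)[1]
  df <- fs / n
  cum_prev <- if (j > 1) cum[j - 1] else 0
  f_prev <- if (j > 1) freqs[j - 1] else freqs[1] - df
  f_prev + (half - cum_prev) / (cum[j] - cum_prev) * (freqs[j] - f_prev)
}

#' Kinematic biomarkers of one session
#'
#' Restricts the session to QC-passed trials whose stretch duration falls in
#' the eligibility window (1-2 s by default, which keeps manual-velocity
#' variation small), runs the constant-jerk reconstruction on each, and
#' averages the three actual-vs-reconstructed Pearson correlations (angle,
#' speed, acceleration) and the median frequency of the actual angular
#' acceleration across eligible trials.
#'
#' @param pts List of `preprocessed_trial` objects (one session).
#' @param window Stretch-duration eligibility window in seconds.
#' @param acc1 First-stage reconstruction peak (deg/s^2).
#' @return A `kinematic_biomarkers` object: `corr_angle`, `corr_speed`,
#'   `corr_acc`, `mdf_acc` (Hz), `n_trials_used`, plus the per-trial tibble.
#' @export
extract_kinematic_biomarkers <- function(pts, window = c(1, 2),
                                         acc1 = 4000) {
  eligible <- purrr::keep(pts, function(p) {
    isTRUE(p$qc_pass) && !is.na(p$stretch_duration) &&
      p$stretch_duration >= window[1] && p$stretch_duration <= window[2]
  })
  if (length(eligible) == 0) {
    abort("no_eligible_trials: no QC-passed trial in the duration window",
          class = "spastr_no_eligible_trials")
  }
  per_trial <- purrr::map_dfr(eligible, function(p) {
    rec <- reconstruct_kinematics(p, acc1 = acc1)
    tibble::tibble(
      trial_id = p$trial_id,
      stretch_duration = p$stretch_duration,
      corr_angle = unname(rec$corr["angle"]),
      corr_speed = unname(rec$corr["speed"]),
      corr_acc = unname(rec$corr["acc"]),
      mdf_acc = median_frequency(rec$actual$acc, fs = p$fs_gyro)
    )
  })
  structure(
    list(
      corr_angle = mean(per_trial$corr_angle),
      corr_speed = mean(per_trial$corr_speed),
      corr_acc = mean(per_trial$corr_acc),
      mdf_acc = mean(per_trial$mdf_acc),
      n_trials_used = nrow(per_trial),
      per_trial = per_trial
    ),
    class = "kinematic_biomarkers"
  )
}

#' @export
print.kinematic_biomarkers <- function(x, ...) {
  cat(sprintf(
    "<kinematic_biomarkers> corr(angle/speed/acc) = %.3f/%.3f/%.3f, MDF = %.2f Hz (%d trials)\n",
    x$corr_angle, x$corr_speed, x$corr_acc, x$mdf_acc, x$n_trials_used))
  invisible(x)
}
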