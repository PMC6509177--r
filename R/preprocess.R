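#' Amplitude-threshold onset/offset detection
#'
#' Detects activity bounds in a non-negative detection signal (an EMG RMS
#' envelope, or the angular-speed magnitude) by the baseline-relative
#' amplitude rule: the threshold is the baseline mean plus `k` baseline
#' standard deviations (k = 3 by default), and an onset is declared at the
#' first run of at least `min_run_s` consecutive supra-threshold samples.
#' The offset is the last sample of that run.
#'
#' With `refine = TRUE` the bounds of the accepted run are walked outwards to
#' the crossing of baseline mean + 1 SD, recovering part of the low-amplitude
#' tails that the 3 SD threshold clips off. This is off by default: on fast
#' stretches the sharp deceleration edge is smeared by the 10 Hz low-pass and
#' the walk then over-extends the window, which costs more accuracy than the
#' clipped tails do.
#'
#' The rule is invariant to adding a constant to the whole signal, because
#' both threshold terms are estimated from the baseline window.
#'
#' @param x Numeric vector, the detection signal.
#' @param fs Sampling rate in Hz.
#' @param baseline_s Length of the baseline window (s), taken from the start
#'   of `x`; must precede any activity.
#' @param k Threshold multiplier (> 0, default 3).
#' @param min_run_s Minimum supra-threshold run length (s) to accept an onset.
#' @param refine Walk bounds outwards to the mean + 1 SD crossing.
#' @return A list with integer elements `onset` and `offset`, or `NULL` when
#'   no qualifying run exists.
#' @export
#' @examples
#' x <- c(rep(0, 100), rep(1, 50), rep(0, 50))
#' detect_bounds(x, fs = 100, baseline_s = 0.5, min_run_s = 0.1)
detect_bounds <- function(x, fs, baseline_s = 0.5, k = 3,
                          min_run_s = 0.025, refine = FALSE) {
  stopifnot(is.numeric(x), is_scalar_num(fs), fs > 0, k > 0)
  nb <- round(baseline_s * fs)
  if (nb >= length(x)) {
    abort(
      paste0("baseline window (", nb, " samples) is not shorter than the ",
             "signal (", length(x), " samples)"),
      class = "spastr_detect_error"
    )
  }
  if (nb < 2L) {
    abort("baseline window must contain at least 2 samples",
          class = "spastr_detect_error")
  }
  mu <- mean(x[seq_len(nb)])
  s <- stats::sd(x[seq_len(nb)])
  thr <- mu + k * s
  above <- x > thr
  r <- rle(above)
  min_run <- max(1L, round(min_run_s * fs))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= min_run)
  if (length(ok) == 0L) {
    return(NULL)
  }
  onset <- starts[ok[1L]]
  offset <- ends[ok[1L]]
  if (refine) {
    thr2 <- mu + s
    while (onset > 1L && x[onset - 1L] > thr2) onset <- onset - 1L
    while (offset < length(x) && x[offset + 1L] > thr2) offset <- offset + 1L
  }
  list(onset = onset, offset = offset)
}

#' Automated quality control of a preprocessed trial
#'
#' Replaces visual screening of contaminated stretch segments with fixed,
#' machine-readable rules. A trial fails when (in this order):
#' \itemize{
#'   \item no movement bounds were detected (`"no_movement"`),
#'   \item the detected stretch duration falls outside
#'     `qc$duration_range` (default 0.3-10 s, `"duration_out_of_range"`),
#'   \item the raw-EMG baseline SD exceeds `qc$baseline_sd_max`
#'     (`"saturated_baseline"`),
#'   \item the fraction of clipped EMG samples (|EMG| at or above
#'     `qc$clip_value`) reaches `qc$clip_frac_max` (`"clipping"`).
#' }
#'
#' @param pt A `preprocessed_trial` (see [preprocess_trial()]).
#' @param qc QC limit list, see `default_config()$preprocess$qc`.
#' @param baseline_s Baseline window (s) used for the baseline-SD check.
#' @return A list with `qc_pass` (logical) and `qc_reason` (string, `"pass"`
#'   when the trial passes).
#' @export
qc_trial <- function(pt, qc = default_config()$preprocess$qc,
                     baseline_s = 0.5) {
  if (is.null(pt$move_on) || is.null(pt$move_off) ||
      is.na(pt$move_on) || is.na(pt$move_off)) {
    return(list(qc_pass = FALSE, qc_reason = "no_movement"))
  }
  dur <- (pt$move_off - pt$move_on) / pt$fs_gyro
  if (dur < qc$duration_range[1] || dur > qc$duration_range[2]) {
    return(list(qc_pass = FALSE, qc_reason = "duration_out_of_range"))
  }
  nb <- round(baseline_s * pt$fs_emg)
  base_sd <- stats::sd(pt$emg[seq_len(min(nb, length(pt$emg)))])
  if (is.finite(base_sd) && base_sd > qc$baseline_sd_max) {
    return(list(qc_pass = FALSE, qc_reason = "saturated_baseline"))
  }
  clip_frac <- mean(abs(pt$emg) >= qc$clip_value)
  if (clip_frac >= qc$clip_frac_max) {
    return(list(qc_pass = FALSE, qc_reason = "clipping"))
  }
  list(qc_pass = TRUE, qc_reason = "pass")
}

#' Preprocess one raw passive-stretch trial
#'
#' Runs the full conditioning chain on a `raw_trial`: zero-phase 20-450 Hz
#' band-pass of the EMG, zero-phase 10 Hz low-pass of each gyroscope axis,
#' angular-speed magnitude, movement-bound detection on the speed channel and
#' EMG-onset detection on the rectified-RMS envelope (both by the 3 SD
#' baseline rule), followed by automated QC. An EMG onset that does not fall
#' inside the detected movement window is discarded.
#'
#' @param trial A `raw_trial`, e.g. from [simulate_trial()] or
#'   [read_session()].
#' @param config Preprocessing block of the configuration, see
#'   `default_config()$preprocess`.
#' @return A `preprocessed_trial` object: a list carrying the filtered EMG
#'   (`emg_f`), its detection envelope, the angular speed at 100 Hz
#'   (`speed`), movement bounds `move_on`/`move_off` (speed time base),
#'   `emg_onset` (EMG time base, `NA` when absent), `mean_speed` (deg/s over
#'   the movement window), `stretch_duration` (s), and the QC verdict.
#' @export
preprocess_trial <- function(trial, config = default_config()$preprocess) {
  stopifnot(inherits(trial, "raw_trial"))
  emg <- trial$emg$emg_mV
  emg_f <- filter_emg(emg, fs = trial$fs_emg)
  gyro_f <- filter_gyro(trial$gyro, fs = trial$fs_gyro)
  speed <- angular_speed(gyro_f)

  mb <- detect_bounds(speed, fs = trial$fs_gyro,
                      baseline_s = config$baseline_s, k = config$k,
                      min_run_s = config$min_run_speed_s)
  env <- emg_envelope(emg_f, fs = trial$fs_emg, window_s = config$envelope_s)
  eb <- detect_bounds(env, fs = trial$fs_emg,
                      baseline_s = config$baseline_s, k = config$k,
                      min_run_s = config$min_run_emg_s)

  move_on <- if (is.null(mb)) NA_integer_ else mb$onset
  move_off <- if (is.null(mb)) NA_integer_ else mb$offset
  emg_onset <- if (is.null(eb)) NA_integer_ else eb$onset

  # keep the EMG onset only when it maps into the movement window
  if (!is.na(emg_onset) && !is.na(move_on)) {
    t_emg <- (emg_onset - 1) / trial$fs_emg
    t_on <- (move_on - 1) / trial$fs_gyro
    t_off <- (move_off - 1) / trial$fs_gyro
    if (t_emg < t_on || t_emg > t_off) emg_onset <- NA_integer_
  } else if (is.na(move_on)) {
    emg_onset <- NA_integer_
  }

  mean_speed <- NA_real_
  stretch_duration <- NA_real_
  if (!is.na(move_on)) {
    mean_speed <- mean(speed[move_on:move_off])
    stretch_duration <- (move_off - move_on) / trial$fs_gyro
  }

  pt <- structure(
    list(
      subject_id = trial$subject_id,
      trial_id = trial$trial_id,
      muscle = trial$muscle,
      emg = emg,
      emg_f = emg_f,
      envelope = env,
      speed = speed,
      fs_emg = trial$fs_emg,
      fs_gyro = trial$fs_gyro,
      move_on = move_on,
      move_off = move_off,
      emg_onset = emg_onset,
      mean_speed = mean_speed,
      stretch_duration = stretch_duration,
      truth = trial$truth
    ),
    class = "preprocessed_trial"
  )
  verdict <- qc_trial(pt, qc = config$qc, baseline_s = config$baseline_s)
  pt$qc_pass <- verdict$qc_pass
  pt$qc_reason <- verdict$qc_reason
  pt
}

#' Preprocess every trial of a session
#'
#' @param trials A list of `raw_trial` objects (one subject's session).
#' @param config Preprocessing configuration block.
#' @return A list of `preprocessed_trial` objects.
#' @export
preprocess_session <- function(trials, config = default_config()$preprocess) {
  lapply(trials, preprocess_trial, config = config)
}

#' Per-trial summary of a preprocessed session
#'
#' @param pts A list of `preprocessed_trial` objects.
#' @return A tibble with one row per trial: QC verdict, mean stretch speed,
#'   stretch duration and whether an EMG onset was found.
#' @export
session_summary <- function(pts) {
  purrr::map_dfr(pts, function(pt) {
    tibble::tibble(
      subject_id = pt$subject_id,
      trial_id = pt$trial_id,
      qc_pass = pt$qc_pass,
      qc_reason = pt$qc_reason,
      mean_speed = pt$mean_speed,
      stretch_duration = pt$stretch_duration,
      has_onset = !is.na(pt$emg_onset)
    )
  })
}

#' @export
print.preprocessed_trial <- function(x, ...) {
  cat("<preprocessed_trial> ", x$subject_id, "/", x$trial_id,
      "  qc: ", x$qc_reason, "\n", sep = "")
  if (!is.na(x$move_on)) {
    cat(sprintf("  stretch %.2f s, mean speed %.1f deg/s, EMG onset: %s\n",
                x$stretch_duration, x$mean_speed,
                ifelse(is.na(x$emg_onset), "none",
                       sprintf("%.3f s", (x$emg_onset - 1) / x$fs_emg))))
  }
  invisible(x)
}
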