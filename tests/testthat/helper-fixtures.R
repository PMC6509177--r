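# Shared fixtures, all built in code.

# One mid-severity subject with fixed parameters (no RNG needed).
fixed_params <- function(grade = "1+", tsrt = 48, slope = -0.25,
                         gain = 0.14, amp = 0.15) {
  structure(
    list(subject_id = "SX", mas_grade = grade,
         tsrt_true = if (grade == "0") 120 else tsrt,
         dsrt_slope = if (grade == "0") 0 else slope,
         perturb_gain = gain,
         emg_burst_amp = if (grade == "0") 0 else amp,
         baseline_sd = 0.008, p_miss = 0, muscle = "BB"),
    class = "sim_subject_params"
  )
}

quick_trial <- function(params = fixed_params(), peak_velocity = 180,
                        rom = 130, seed = 42, duration = NULL, ...) {
  duration <- duration %||% min(7, max(3, 2 * rom / peak_velocity + 1.6))
  simulate_trial(params,
                 list(duration = duration, peak_velocity = peak_velocity,
                      rom = rom, seed = seed, ...))
}

# Analytic constant-jerk speed profile sampled at fs (deg/s); used to build
# noise-free preprocessed trials without the generator.
cj_speed <- function(vmax, t1, t2, fs = 100) {
  tt <- seq(0, t1 + t2, by = 1 / fs)
  s <- numeric(length(tt))
  r1 <- tt <= t1
  x <- tt[r1] / t1
  s[r1] <- ifelse(x <= 0.5, 2 * vmax * x^2, vmax - 2 * vmax * (1 - x)^2)
  x <- (tt[!r1] - t1) / t2
  s[!r1] <- ifelse(x <= 0.5, vmax - 2 * vmax * x^2, 2 * vmax * (1 - x)^2)
  s
}

# Minimal hand-built preprocessed trial around a given speed series.
fake_pt <- function(speed, move_on = 1L, move_off = length(speed),
                    emg_onset = NA_integer_, qc_pass = TRUE,
                    stretch_duration = (move_off - move_on) / 100,
                    trial_id = "tX") {
  structure(
    list(subject_id = "SX", trial_id = trial_id, muscle = "BB",
         emg = numeric(0), emg_f = numeric(0), envelope = numeric(0),
         speed = speed, fs_emg = 1000L, fs_gyro = 100L,
         move_on = as.integer(move_on), move_off = as.integer(move_off),
         emg_onset = emg_onset,
         mean_speed = mean(speed[move_on:move_off]),
         stretch_duration = stretch_duration,
         qc_pass = qc_pass, qc_reason = if (qc_pass) "pass" else "fail",
         truth = NULL),
    class = "preprocessed_trial"
  )
}

# Analytic magnitude response of a digital Butterworth filter designed by the
# bilinear transform with prewarped edges, evaluated at frequency f. Squared
# for a forward-backward (zero-phase) pass. Independent of the coefficients
# signal::butter produces.
butter_gain_lp <- function(f, fc, fs, order, zero_phase = TRUE) {
  warp <- function(x) tan(pi * x / fs)
  g2 <- 1 / (1 + (warp(f) / warp(fc))^(2 * order))
  if (zero_phase) g2 else sqrt(g2)
}

butter_gain_bp <- function(f, f1, f2, fs, order, zero_phase = TRUE) {
  warp <- function(x) tan(pi * x / fs)
  w <- warp(f); w1 <- warp(f1); w2 <- warp(f2)
  g2 <- 1 / (1 + ((w^2 - w1 * w2) / (w * (w2 - w1)))^(2 * order))
  if (zero_phase) g2 else sqrt(g2)
}

# Amplitude of a steady sinusoid after filtering, measured over the middle
# half of a long record.
measured_gain <- function(filter_fun, f, fs, n_sec = 8) {
  t <- seq(0, n_sec, by = 1 / fs)
  y <- filter_fun(sin(2 * pi * f * t))
  mid <- y[round(length(y) * 0.25):round(length(y) * 0.75)]
  sqrt(2) * sqrt(mean(mid^2))
}
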