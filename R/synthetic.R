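# Synthetic passive-stretch simulator.
#
# The generator encodes the two premises the downstream models rest on:
# (i) the dynamic stretch reflex threshold decreases linearly with stretch
# velocity (lambda premise), and (ii) the stretch kinematics deviate from a
# constant-jerk pattern by an amount that grows with spasticity severity
# (kinematic premise). Severity enters through grade-conditional parameter
# distributions; all randomness is derived from explicit seeds.

#' Draw subject-level simulation parameters for one MAS grade
#'
#' Draws a subject's generative parameters from the grade-conditional
#' distributions in the configuration: the true tonic stretch reflex
#' threshold `tsrt_true` (deg; 120 exactly for grade 0), the velocity
#' sensitivity `dsrt_slope` (deg per deg/s, <= 0), the severity-scaled
#' acceleration fluctuation gain `perturb_gain`, the EMG burst amplitude and
#' baseline noise SD (mV). Uses the current RNG state; seed upstream (e.g.
#' via [simulate_cohort()]) for reproducibility.
#'
#' @param subject_id Subject identifier string.
#' @param mas_grade One of `"0"`, `"1"`, `"1+"`, `"2"`, `"3"`.
#' @param config Simulation configuration block
#'   (`default_config()$simulate`).
#' @return A `sim_subject_params` list.
#' @export
sim_subject_params <- function(subject_id, mas_grade,
                               config = default_config()$simulate) {
  mas_grade <- as.character(mas_grade)
  gp <- config$grade_params[[mas_grade]]
  if (is.null(gp)) {
    abort(paste0("unsupported MAS grade: ", mas_grade),
          class = "spastr_grade_error")
  }
  if (mas_grade == "0") {
    tsrt <- 120
    slope <- 0
    amp <- 0
  } else {
    tsrt <- min(119, max(5, rnorm(1, gp$tsrt_mean, gp$tsrt_sd)))
    sf <- runif(1, config$slope_frac_range[1], config$slope_frac_range[2])
    slope <- -tsrt * sf / 135
    amp <- gp$burst_amp * exp(rnorm(1, 0, 0.15))
  }
  gain <- gp$perturb_mean * exp(rnorm(1, 0, gp$perturb_sdlog))
  muscle <- if (mas_grade == "0") "BB" else
    sample(c("BB", "TB"), 1, prob = c(0.75, 0.25))
  structure(
    list(
      subject_id = subject_id,
      mas_grade = mas_grade,
      tsrt_true = tsrt,
      dsrt_slope = slope,
      perturb_gain = gain,
      emg_burst_amp = amp,
      baseline_sd = config$baseline_sd,
      p_miss = if (mas_grade == "0") 0 else config$p_miss,
      muscle = muscle
    ),
    class = "sim_subject_params"
  )
}

#' Simulate one passive elbow-stretch trial
#'
#' Generates one trial deterministically from `spec$seed`: a 3-axis
#' gyroscope record at 100 Hz whose magnitude follows a constant-jerk
#' (piecewise-linear acceleration) stretch profile plus band-limited
#' (2-15 Hz) zero-mean acceleration fluctuations with amplitude proportional
#' to `perturb_gain`, and a 1000 Hz EMG record of Gaussian baseline noise
#' plus, when the reflex fires, an amplitude-modulated 20-450 Hz burst with a
#' 50 ms rise. The burst starts when the traversed angle first exceeds
#' `DSRT(v) = tsrt_true + dsrt_slope * v`, with `v` the mean stretch speed;
#' no burst is emitted when that angle exceeds the range of motion, for
#' grade-0 subjects below the healthy velocity threshold, or (with
#' probability `p_miss`) to emulate trials without an evoked response.
#'
#' @param params A `sim_subject_params` object.
#' @param spec A list with `duration` (total trial length, s, in \[3, 7\]),
#'   `peak_velocity` (deg/s), `rom` (deg, in \[120, 140\]), optional
#'   `t1_frac` (accelerating fraction of the stretch, default 0.5) and
#'   integer `seed`.
#' @param config Simulation configuration block.
#' @return A `raw_trial`: list with tibbles `emg` (`time_s`, `emg_mV`) and
#'   `gyro` (`time_s`, `gx`, `gy`, `gz` in deg/s), metadata, and a `truth`
#'   block recording the generative quantities (programmed mean speed, DSRT
#'   applied, burst onset time) for validation studies.
#' @export
simulate_trial <- function(params, spec, config = default_config()$simulate) {
  stopifnot(inherits(params, "sim_subject_params"))
  dur <- spec$duration
  vmax <- spec$peak_velocity
  rom <- spec$rom
  t1f <- spec$t1_frac %||% 0.5
  if (!is_scalar_num(dur) || dur < 3 || dur > 7) {
    abort("trial duration must lie in [3, 7] s",
          class = "spastr_invalid_spec")
  }
  if (!is_scalar_num(rom) || rom < 120 || rom > 140) {
    abort("range of motion must lie in [120, 140] degrees",
          class = "spastr_invalid_spec")
  }
  if (!is_scalar_num(vmax) || vmax <= 0) {
    abort("peak velocity must be positive", class = "spastr_invalid_spec")
  }
  stretch_t <- 2 * rom / vmax      # constant-jerk: mean speed = vmax / 2
  t0 <- config$pre_rest
  if (t0 + stretch_t + 0.5 > dur) {
    abort(sprintf(
      "duration %.2f s too short for a %.2f s stretch plus rest",
      dur, stretch_t), class = "spastr_invalid_spec")
  }
  if (is.null(spec$seed)) {
    abort("trial spec must carry an integer seed",
          class = "spastr_invalid_spec")
  }

  withr::with_seed(as.integer(spec$seed), {
    fs_g <- 100L
    fs_e <- 1000L
    n_g <- round(dur * fs_g)
    tg <- (seq_len(n_g) - 1) / fs_g
    t1 <- t1f * stretch_t
    t2 <- stretch_t - t1
    a1p <- 2 * vmax / t1
    a2p <- 2 * vmax / t2

    tau <- tg - t0
    acc <- numeric(n_g)
    in1 <- tau >= 0 & tau <= t1
    in2 <- tau > t1 & tau <= stretch_t
    acc[in1] <- a1p * (1 - abs(2 * tau[in1] / t1 - 1))
    acc[in2] <- -a2p * (1 - abs(2 * (tau[in2] - t1) / t2 - 1))

    # band-limited severity perturbation on the acceleration, stretch only
    idx <- which(tau >= 0 & tau <= stretch_t)
    z <- rnorm(n_g)
    bp <- signal::butter(2, c(2, 15) / (fs_g / 2), type = "pass")
    zb <- zero_phase_filter(bp, z)[idx]
    zb <- zb / stats::sd(zb)
    ramp <- pmin(1, pmin(seq_along(idx) - 1, rev(seq_along(idx)) - 1) / 5)
    acc[idx] <- acc[idx] +
      params$perturb_gain * max(a1p, a2p) * zb * ramp

    # exact zero net velocity over the stretch (trapezoid sense)
    speed <- cumtrapz_int(tg, acc)
    resid <- speed[idx[length(idx)]]
    acc[idx] <- acc[idx] - resid / ((length(idx) - 1) / fs_g)
    speed <- cumtrapz_int(tg, acc)
    speed[tau > stretch_t] <- 0

    theta <- cumtrapz_int(tg, speed)
    rom_sim <- theta[idx[length(idx)]] - theta[idx[1]]
    v_mean <- rom_sim / stretch_t

    u <- c(0.15, 0.10, 0.98)
    u <- u / sqrt(sum(u^2))
    gyro <- outer(speed, u) +
      matrix(rnorm(3 * n_g, 0, config$gyro_noise_sd), ncol = 3)

    # EMG channel
    n_e <- round(dur * fs_e)
    emg <- rnorm(n_e, 0, params$baseline_sd)
    dsrt_applied <- NA_real_
    onset_time <- NA_real_
    has_burst <- FALSE
    fire <- TRUE
    if (params$mas_grade == "0" &&
        v_mean < config$healthy_velocity_threshold) fire <- FALSE
    if (fire) {
      dsrt_t <- params$tsrt_true + params$dsrt_slope * v_mean +
        rnorm(1, 0, config$dsrt_jitter_sd)
      dsrt_t <- max(dsrt_t, 0.5)
      if (dsrt_t >= rom_sim) fire <- FALSE
      if (fire && runif(1) < params$p_miss) fire <- FALSE
      if (fire) {
        rel <- theta - theta[idx[1]]
        j <- which(rel[idx] >= dsrt_t)[1] + idx[1] - 1L
        if (is.na(j) || j <= idx[1]) {
          fire <- FALSE
        } else {
          # linear interpolation of the crossing time between gyro samples
          frac <- (dsrt_t - rel[j - 1L]) / (rel[j] - rel[j - 1L])
          onset_time <- tg[j - 1L] + frac / fs_g
          i_on <- round(onset_time * fs_e) + 1L
          i_end <- min(n_e, round((t0 + stretch_t + 0.15) * fs_e))
          len <- i_end - i_on + 1L
          if (len > 200L) {
            carrier <- rnorm(len)
            carrier <- filter_emg(carrier, fs = fs_e)
            carrier <- carrier / stats::sd(carrier)
            rise <- min(len, 50L)
            decay <- min(len, 100L)
            env <- rep(1, len)
            env[seq_len(rise)] <- seq(0, 1, length.out = rise)
            env[(len - decay + 1L):len] <- seq(1, 0, length.out = decay)
            emg[i_on:i_end] <- emg[i_on:i_end] +
              params$emg_burst_amp * env * carrier
            dsrt_applied <- dsrt_t
            has_burst <- TRUE
          }
        }
      }
    }

    structure(
      list(
        emg = tibble::tibble(time_s = (seq_len(n_e) - 1) / fs_e,
                             emg_mV = emg),
        gyro = tibble::tibble(time_s = tg,
                              gx = gyro[, 1], gy = gyro[, 2],
                              gz = gyro[, 3]),
        subject_id = params$subject_id,
        trial_id = sprintf("t%09d", as.integer(spec$seed)),
        muscle = params$muscle,
        fs_emg = fs_e,
        fs_gyro = fs_g,
        truth = list(
          mean_speed = rom / stretch_t,
          mean_speed_sim = v_mean,
          rom = rom,
          rom_sim = rom_sim,
          stretch_start = t0,
          stretch_duration = stretch_t,
          t1 = t1,
          t2 = t2,
          dsrt_applied = dsrt_applied,
          onset_time = onset_time,
          has_burst = has_burst
        )
      ),
      class = "raw_trial"
    )
  })
}

#' Simulate a cohort of passive-stretch sessions
#'
#' Draws `n_subjects` subjects with grades from `grade_counts` (by default
#' the 24-subject tally 8 x grade 0, 4 x 1, 6 x 1+, 4 x 2, 2 x 3), gives each
#' a session of 15-20 trials whose peak velocities span slow to fast
#' (60-270 deg/s by default) so the DSRT-velocity regression is
#' well-conditioned, and generates every trial deterministically from seeds
#' derived from `master_seed`.
#'
#' @param n_subjects Number of subjects (>= 2; LOOCV is undefined below 2).
#' @param grade_counts Named integer vector of MAS-grade counts. When the
#'   counts do not sum to `n_subjects` they are used as sampling weights.
#' @param master_seed Integer master seed; the sole source of randomness.
#' @param config Simulation configuration block.
#' @return A `spastr_cohort` tibble with columns `subject_id`, `mas_grade`,
#'   `params` (list of `sim_subject_params`) and `trials` (list of lists of
#'   `raw_trial`).
#' @export
#' @examples
#' co <- simulate_cohort(n_subjects = 2,
#'                       grade_counts = c("0" = 1, "2" = 1),
#'                       master_seed = 7)
#' nrow(co)
simulate_cohort <- function(n_subjects = 24L,
                            grade_counts = default_config()$grade_counts,
                            master_seed = 1L,
                            config = default_config()$simulate) {
  if (!is_scalar_num(n_subjects) || n_subjects < 2) {
    abort("need at least 2 subjects (leave-one-out is undefined otherwise)",
          class = "spastr_invalid_spec")
  }
  grades_all <- c("0", "1", "1+", "2", "3")
  if (!all(names(grade_counts) %in% grades_all)) {
    abort("grade_counts names must be among {0, 1, 1+, 2, 3}",
          class = "spastr_grade_error")
  }
  withr::with_seed(as.integer(master_seed), {
    if (sum(grade_counts) == n_subjects) {
      grades <- rep(names(grade_counts), times = grade_counts)
    } else {
      grades <- sample(names(grade_counts), n_subjects, replace = TRUE,
                       prob = grade_counts / sum(grade_counts))
    }
    rows <- purrr::map(seq_len(n_subjects), function(i) {
      sid <- sprintf("S%02d", i)
      params <- sim_subject_params(sid, grades[i], config)
      n_trials <- sample(config$trials_min:config$trials_max, 1)
      vr <- config$peak_velocity_range
      vmax <- seq(vr[1], vr[2], length.out = n_trials) + rnorm(n_trials, 0, 5)
      vmax <- pmin(pmax(vmax, vr[1] - 10), vr[2] + 20)
      seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
      trials <- purrr::map(seq_len(n_trials), function(k) {
        rom <- runif(1, config$rom_range[1], config$rom_range[2])
        vk <- max(vmax[k], 2 * rom / 5.4)  # stretch must fit a 7 s trial
        stretch_t <- 2 * rom / vk
        dur <- min(7, max(3, ceiling((stretch_t + 1.6) * 2) / 2))
        spec <- list(
          duration = dur,
          peak_velocity = vk,
          rom = rom,
          t1_frac = runif(1, config$t1_frac_range[1],
                          config$t1_frac_range[2]),
          seed = seeds[k]
        )
        simulate_trial(params, spec, config)
      })
      tibble::tibble(subject_id = sid, mas_grade = grades[i],
                     params = list(params), trials = list(trials))
    })
    out <- dplyr::bind_rows(rows)
    class(out) <- c("spastr_cohort", class(out))
    attr(out, "master_seed") <- as.integer(master_seed)
    out
  })
}

#' Simulate noisy DSRT-velocity points for one subject
#'
#' Generates dynamic stretch reflex threshold observations directly at the
#' regression level: `dsrt = tsrt_true + dsrt_slope * v + e`, with
#' `e ~ N(0, noise_sd)` and mean speeds spread over `speed_range`. Used for
#' threshold-recovery studies of [fit_lambda()] that isolate the regression
#' from signal-level detection noise.
#'
#' @param tsrt_true True tonic threshold (deg).
#' @param dsrt_slope Velocity sensitivity (deg per deg/s, <= 0).
#' @param n_trials Number of points.
#' @param speed_range Range of mean stretch speeds (deg/s).
#' @param noise_sd SD of the additive DSRT noise (deg).
#' @param seed Integer seed.
#' @return A tibble of `DsrtPoint` rows (`mean_speed`, `dsrt`, `trial_id`).
#' @export
simulate_dsrt_points <- function(tsrt_true, dsrt_slope, n_trials = 15,
                                 speed_range = c(30, 135), noise_sd = 3,
                                 seed = 1L) {
  withr::with_seed(as.integer(seed), {
    v <- seq(speed_range[1], speed_range[2], length.out = n_trials) +
      rnorm(n_trials, 0, 2)
    v <- pmax(v, 1)
    dsrt <- tsrt_true + dsrt_slope * v + rnorm(n_trials, 0, noise_sd)
    tibble::tibble(
      mean_speed = v,
      dsrt = pmin(pmax(dsrt, 0), 140),
      trial_id = sprintf("p%02d", seq_len(n_trials))
    )
  })
}

#' @export
print.raw_trial <- function(x, ...) {
  cat("<raw_trial> ", x$subject_id, "/", x$trial_id, " (", x$muscle, ")\n",
      sprintf("  EMG %d samples @ %d Hz, gyro %d samples @ %d Hz\n",
              nrow(x$emg), x$fs_emg, nrow(x$gyro), x$fs_gyro), sep = "")
  invisible(x)
}
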