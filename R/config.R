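#' Default analysis and simulation configuration
#'
#' Returns the nested configuration list used by [simulate_cohort()],
#' [preprocess_trial()], [extract_features()] and [run_pipeline()]. Every
#' numeric constant of the framework is surfaced here so that a single YAML
#' file (see [read_config()]) can override any of them.
#'
#' The blocks are:
#' \describe{
#'   \item{simulate}{Grade-conditional parameter distributions of the
#'     synthetic cohort generator and the per-trial stretch geometry.}
#'   \item{preprocess}{Filter-independent detection settings: the
#'     baseline window (s), the threshold multiplier `k` (3 times the
#'     baseline SD), minimum run lengths for the EMG and speed channels,
#'     the 50 ms RMS envelope window, and the automated QC limits.}
#'   \item{lambda}{Majority threshold governing the 120-degree TSRT
#'     fallback and the prediction-interval level for outlier exclusion.}
#'   \item{kinematic}{First-stage reconstruction peak `acc1` (deg/s^2) and
#'     the trial-duration eligibility window (s).}
#'   \item{svr}{SVR settings used by the evaluation pipeline: the published
#'     constants C = 30 and epsilon = 0.09 on raw (unstandardized) features.
#'     The published kernel width 0.007 is stated without a convention; under
#'     this package's `exp(-d^2/(2 sigma^2))` kernel it would collapse the
#'     Gram matrix to the identity on any realistic feature scale, so the
#'     pipeline reads it as the common library convention `exp(-gamma d^2)`
#'     with `gamma = 0.007` and sets `sigma = 1/sqrt(2 * 0.007)`, which is
#'     the identical kernel. [svr_config()] itself defaults to the constants
#'     exactly as printed.}
#'   \item{evaluate}{Methods run by the cross-validation harness.}
#' }
#'
#' @return A named nested list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$svr$penalty_c
default_config <- function() {
  list(
    seed = 1L,
    n_subjects = 24L,
    grade_counts = c("0" = 8L, "1" = 4L, "1+" = 6L, "2" = 4L, "3" = 2L),
    simulate = list(
      grade_params = list(
        "0"  = list(tsrt_mean = 120, tsrt_sd = 0, perturb_mean = 0.03,
                    perturb_sdlog = 0.2, burst_amp = 0.00),
        "1"  = list(tsrt_mean = 55, tsrt_sd = 6, perturb_mean = 0.10,
                    perturb_sdlog = 0.2, burst_amp = 0.10),
        "1+" = list(tsrt_mean = 48, tsrt_sd = 6, perturb_mean = 0.14,
                    perturb_sdlog = 0.2, burst_amp = 0.12),
        "2"  = list(tsrt_mean = 40, tsrt_sd = 6, perturb_mean = 0.20,
                    perturb_sdlog = 0.2, burst_amp = 0.15),
        "3"  = list(tsrt_mean = 25, tsrt_sd = 6, perturb_mean = 0.30,
                    perturb_sdlog = 0.2, burst_amp = 0.20)
      ),
      slope_frac_range = c(0.4, 0.7),
      trials_min = 15L,
      trials_max = 20L,
      peak_velocity_range = c(60, 270),
      rom_range = c(120, 140),
      t1_frac_range = c(0.42, 0.58),
      baseline_sd = 0.008,
      gyro_noise_sd = 0.1,
      dsrt_jitter_sd = 2,
      p_miss = 0.05,
      healthy_velocity_threshold = 350,
      pre_rest = 1.0
    ),
    preprocess = list(
      k = 3,
      baseline_s = 0.5,
      min_run_emg_s = 0.025,
      min_run_speed_s = 0.3,
      envelope_s = 0.05,
      qc = list(
        duration_range = c(0.3, 10),
        baseline_sd_max = 0.5,
        clip_value = 2.4,
        clip_frac_max = 0.05
      )
    ),
    lambda = list(majority = 0.5, level = 0.95, fallback_tsrt = 120),
    kinematic = list(acc1 = 4000, window = c(1, 2)),
    svr = list(
      penalty_c = 30,
      epsilon = 0.09,
      # the published width 0.007 is only usable as a library-convention
      # gamma (exp(-gamma d^2)) on the raw feature scale; expressed in this
      # package's exp(-d^2 / (2 sigma^2)) convention the same kernel is
      # sigma = 1 / sqrt(2 * 0.007)
      sigma = 1 / sqrt(2 * 0.007),
      standardize_features = FALSE
    ),
    evaluate = list(methods = c("lambda", "kinematic", "fusion"))
  )
}

#' Read a YAML configuration file
#'
#' Reads a YAML file whose blocks mirror [default_config()] and merges it
#' recursively over the defaults, so a file needs to state only the values it
#' changes.
#'
#' @param path Path to a YAML file.
#' @return The merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "spastr_io_error")
  }
  user <- yaml::read_yaml(path)
  modify_defaults(default_config(), user)
}

# recursive list merge: values in `user` override `base`
modify_defaults <- function(base, user) {
  if (!is.list(user)) return(user)
  for (nm in names(user)) {
    if (nm %in% names(base) && is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- modify_defaults(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}
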