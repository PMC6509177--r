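# Session storage: one directory per subject with a manifest.json and
# plain-CSV traces per trial (emg_<id>.csv: time_s, emg_mV; gyro_<id>.csv:
# time_s, gx, gy, gz in deg/s). CSV keeps the layout language-neutral and
# inspectable.

#' Write one subject's session to a directory
#'
#' @param trials List of `raw_trial` objects.
#' @param dir Target directory (created if needed).
#' @param subject_id,mas_grade,muscle Session metadata; defaults are taken
#'   from the first trial where possible.
#' @param provenance `"simulated"` or `"recorded"`, stored in the manifest.
#' @return `dir`, invisibly.
#' @export
write_session <- function(trials, dir, subject_id = NULL, mas_grade = NULL,
                          muscle = NULL, provenance = "simulated") {
  stopifnot(length(trials) >= 1)
  subject_id <- subject_id %||% trials[[1]]$subject_id
  muscle <- muscle %||% trials[[1]]$muscle
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(trials, function(tr) {
    emg_file <- paste0("emg_", tr$trial_id, ".csv")
    gyro_file <- paste0("gyro_", tr$trial_id, ".csv")
    readr::write_csv(tr$emg, file.path(dir, emg_file))
    readr::write_csv(tr$gyro, file.path(dir, gyro_file))
    list(trial_id = tr$trial_id, emg_file = emg_file, gyro_file = gyro_file,
         fs_emg = tr$fs_emg, fs_gyro = tr$fs_gyro)
  })
  manifest <- list(
    subject_id = subject_id,
    mas_grade = mas_grade,
    muscle = muscle,
    provenance = provenance,
    trials = entries
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

check_timebase <- function(time_s, fs) {
  d <- diff(time_s)
  if (any(d <= 0)) return("bad_timebase")
  if (abs(stats::median(d) - 1 / fs) > 1e-6) return("rate_mismatch")
  NULL
}

#' Read one subject's session from a directory
#'
#' Validates the manifest, loads every trial's EMG and gyroscope CSVs with
#' their declared sampling rates, and skips malformed trials (non-monotone
#' time stamps, sampling-rate mismatch) with a recorded reason.
#'
#' @param dir Session directory containing `manifest.json`.
#' @return A list with `manifest`, `trials` (list of `raw_trial`),
#'   `mas_grade` and a `skipped` tibble (trial_id, reason).
#' @export
read_session <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    abort(paste0("missing manifest: ", mpath), class = "spastr_io_error")
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  skipped <- list()
  trials <- list()
  for (entry in manifest$trials) {
    emg_path <- file.path(dir, entry$emg_file)
    gyro_path <- file.path(dir, entry$gyro_file)
    for (p in c(emg_path, gyro_path)) {
      if (!file.exists(p)) {
        abort(paste0("manifest references a missing file: ", p),
              class = "spastr_io_error")
      }
    }
    emg <- readr::read_csv(emg_path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "d"))
    gyro <- readr::read_csv(gyro_path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "d"))
    if (!all(c("time_s", "emg_mV") %in% names(emg)) ||
        !all(c("time_s", "gx", "gy", "gz") %in% names(gyro))) {
      abort(paste0("unexpected columns in trial ", entry$trial_id,
                   " (expected time_s/emg_mV and time_s/gx/gy/gz)"),
            class = "spastr_io_error")
    }
    bad <- check_timebase(emg$time_s, entry$fs_emg) %||%
      check_timebase(gyro$time_s, entry$fs_gyro)
    if (!is.null(bad)) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(trial_id = entry$trial_id, reason = bad)
      next
    }
    trials[[length(trials) + 1L]] <- structure(
      list(
        emg = emg, gyro = gyro,
        subject_id = manifest$subject_id,
        trial_id = entry$trial_id,
        muscle = manifest$muscle %||% "BB",
        fs_emg = entry$fs_emg, fs_gyro = entry$fs_gyro,
        truth = NULL
      ),
      class = "raw_trial"
    )
  }
  list(
    manifest = manifest,
    mas_grade = manifest$mas_grade,
    trials = trials,
    skipped = if (length(skipped)) dplyr::bind_rows(skipped) else
      tibble::tibble(trial_id = character(), reason = character())
  )
}

#' Write a whole cohort to a directory tree
#'
#' One sub-directory per subject, each in the [write_session()] layout.
#'
#' @param cohort A `spastr_cohort` tibble.
#' @param dir Target root directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    write_session(cohort$trials[[i]],
                  file.path(dir, cohort$subject_id[i]),
                  subject_id = cohort$subject_id[i],
                  mas_grade = cohort$mas_grade[i])
  }
  invisible(dir)
}

#' Read a cohort directory tree
#'
#' @param dir Root directory whose sub-directories are sessions.
#' @return A `spastr_cohort` tibble (without generative parameters).
#' @export
read_cohort <- function(dir) {
  subs <- list.dirs(dir, recursive = FALSE)
  subs <- subs[file.exists(file.path(subs, "manifest.json"))]
  if (length(subs) == 0) {
    abort(paste0("no sessions found under ", dir), class = "spastr_io_error")
  }
  rows <- purrr::map(subs, function(d) {
    s <- read_session(d)
    tibble::tibble(subject_id = s$manifest$subject_id,
                   mas_grade = as.character(s$mas_grade),
                   params = list(NULL),
                   trials = list(s$trials))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("spastr_cohort", class(out))
  out
}
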