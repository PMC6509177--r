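# Per-subject feature extraction and the leave-one-out evaluation harness.

method_features <- function(method) {
  switch(method,
    lambda = "tsrt",
    kinematic = c("corr_angle", "corr_speed", "corr_acc", "mdf_acc"),
    fusion = c("tsrt", "corr_angle", "corr_speed", "corr_acc", "mdf_acc"),
    abort(paste0("unknown method: ", method), class = "spastr_eval_error")
  )
}

#' Extract the per-subject feature table of a cohort
#'
#' Runs preprocessing, the lambda model and the kinematic model on every
#' subject's session and assembles the five-dimensional feature vector
#' (TSRT; three actual-vs-reconstructed correlations; median frequency of the
#' angular acceleration) together with the numeric MAS label. Subjects whose
#' kinematic biomarkers cannot be computed (no eligible trial) get `NA`
#' biomarkers and are excluded per-method later, with a reason.
#'
#' @param cohort A `spastr_cohort` tibble ([simulate_cohort()] /
#'   [read_cohort()]).
#' @param config Full configuration list ([default_config()]).
#' @return A tibble with one row per subject: `subject_id`, `mas_grade`,
#'   `label`, `tsrt`, `lambda_slope`, `lambda_r2`, `fallback_used`,
#'   `corr_angle`, `corr_speed`, `corr_acc`, `mdf_acc`, `n_trials_used`,
#'   `n_qc_passed`.
#' @export
extract_features <- function(cohort, config = default_config()) {
  stopifnot(is.data.frame(cohort),
            all(c("subject_id", "mas_grade", "trials") %in% names(cohort)))
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    pts <- preprocess_session(cohort$trials[[i]], config$preprocess)
    n_qc <- sum(purrr::map_lgl(pts, function(p) isTRUE(p$qc_pass)))
    lam <- extract_tsrt(pts,
                        majority = config$lambda$majority,
                        level = config$lambda$level,
                        fallback_tsrt = config$lambda$fallback_tsrt)
    kin <- tryCatch(
      extract_kinematic_biomarkers(pts,
                                   window = config$kinematic$window,
                                   acc1 = config$kinematic$acc1),
      spastr_no_eligible_trials = function(e) NULL
    )
    tibble::tibble(
      subject_id = cohort$subject_id[i],
      mas_grade = cohort$mas_grade[i],
      label = encode_mas(cohort$mas_grade[i]),
      tsrt = lam$intercept_tsrt,
      lambda_slope = lam$slope,
      lambda_r2 = lam$r2,
      fallback_used = lam$fallback_used,
      corr_angle = if (is.null(kin)) NA_real_ else kin$corr_angle,
      corr_speed = if (is.null(kin)) NA_real_ else kin$corr_speed,
      corr_acc = if (is.null(kin)) NA_real_ else kin$corr_acc,
      mdf_acc = if (is.null(kin)) NA_real_ else kin$mdf_acc,
      n_trials_used = if (is.null(kin)) 0L else kin$n_trials_used,
      n_qc_passed = n_qc
    )
  })
}

#' Leave-one-out cross-validated spasticity scores
#'
#' Scores every subject with a model trained on all remaining subjects, for
#' one or more of the three calibration methods:
#' \describe{
#'   \item{lambda}{single-variable linear regression on the TSRT,}
#'   \item{kinematic}{multivariate linear regression on the four kinematic
#'     biomarkers,}
#'   \item{fusion}{epsilon-SVR on the concatenated five-dimensional feature
#'     vector.}
#' }
#' Scores are continuous and unclipped. Subjects with missing features for a
#' method are excluded from that method with a logged reason. When features
#' are standardized for the SVR, the z-scoring statistics come from the
#' training fold only.
#'
#' @param features Feature tibble from [extract_features()] (needs
#'   `subject_id`, `label` and the feature columns).
#' @param methods Subset of `c("lambda", "kinematic", "fusion")` or `"all"`.
#' @param svr An [svr_config()] used by the fusion method.
#' @return A `spastr_eval` object: tibbles `scores` (subject, label, method,
#'   score), `mse` (per method) and `excluded`.
#' @export
loocv <- function(features, methods = "all", svr = svr_config()) {
  stopifnot(is.data.frame(features),
            all(c("subject_id", "label") %in% names(features)))
  if (identical(methods, "all")) {
    methods <- c("lambda", "kinematic", "fusion")
  }
  if (nrow(features) < 2) {
    abort("leave-one-out needs at least 2 subjects",
          class = "spastr_eval_error")
  }
  scores <- list()
  excluded <- list()
  for (m in methods) {
    cols <- method_features(m)
    ok <- stats::complete.cases(features[, c(cols, "label")])
    if (any(!ok)) {
      excluded[[m]] <- tibble::tibble(
        method = m,
        subject_id = features$subject_id[!ok],
        reason = "missing_features"
      )
    }
    fx <- features[ok, , drop = FALSE]
    n <- nrow(fx)
    if (n < 2) {
      abort(paste0("method ", m, ": fewer than 2 subjects with complete ",
                   "features"), class = "spastr_eval_error")
    }
    preds <- vapply(seq_len(n), function(i) {
      tr <- fx[-i, , drop = FALSE]
      te <- fx[i, , drop = FALSE]
      if (m == "lambda") {
        fit <- fit_linear(tr$tsrt, tr$label)
        predict(fit, te$tsrt)
      } else if (m == "kinematic") {
        fit <- fit_multilinear(tr[, cols, drop = FALSE], tr$label)
        predict(fit, te[, cols, drop = FALSE])
      } else {
        fit <- fit_svr(tr[, cols, drop = FALSE], tr$label, config = svr)
        predict(fit, te[, cols, drop = FALSE])
      }
    }, numeric(1))
    scores[[m]] <- tibble::tibble(
      subject_id = fx$subject_id,
      label = fx$label,
      method = m,
      score = preds
    )
  }
  scores <- dplyr::bind_rows(scores)
  mse <- scores |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(mse = mse_score(.data$score, .data$label),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(
      scores = scores,
      mse = mse,
      excluded = if (length(excluded)) dplyr::bind_rows(excluded) else
        tibble::tibble(method = character(), subject_id = character(),
                       reason = character()),
      svr_config = svr
    ),
    class = "spastr_eval"
  )
}

#' @export
print.spastr_eval <- function(x, ...) {
  cat("<spastr_eval> leave-one-out evaluation\n")
  for (i in seq_len(nrow(x$mse))) {
    cat(sprintf("  %-9s MSE = %.4f  (n = %d)\n",
                x$mse$method[i], x$mse$mse[i], x$mse$n[i]))
  }
  if (nrow(x$excluded)) {
    cat("  excluded:", nrow(x$excluded), "subject-method pair(s)\n")
  }
  invisible(x)
}
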