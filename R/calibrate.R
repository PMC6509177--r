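# Calibration of biomarkers to the modified Ashworth scale (MAS).

#' Numeric encoding of MAS grades
#'
#' Maps the ordinal grades to the numeric scores used as regression labels:
#' 0 -> 0, 1 -> 1, 1+ -> 1.5, 2 -> 2, 3 -> 3. Grade 4 (and anything else) is
#' rejected: muscles at grade 4 cannot complete the passive-stretch protocol.
#'
#' @param grade Character (or factor) vector of MAS grades.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' encode_mas(c("0", "1+", "3")) # 0 1.5 3
encode_mas <- function(grade) {
  map <- c("0" = 0, "1" = 1, "1+" = 1.5, "2" = 2, "3" = 3)
  grade <- as.character(grade)
  bad <- !grade %in% names(map)
  if (any(bad)) {
    abort(paste0("unsupported MAS grade(s): ",
                 paste(unique(grade[bad]), collapse = ", ")),
          class = "spastr_grade_error")
  }
  unname(map[grade])
}

#' Single-variable linear calibration
#'
#' Ordinary least squares of numeric MAS labels on one biomarker (the TSRT in
#' the lambda method). Predictions are the unclipped line values.
#'
#' @param x Numeric feature vector (>= 2 distinct values).
#' @param y Numeric labels, same length.
#' @return A `spastr_linear` object with `slope` and `intercept`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 2 || stats::sd(x) == 0) {
    abort("linear calibration needs >= 2 distinct feature values",
          class = "spastr_calibrate_error")
  }
  fit <- lm(y ~ x)
  structure(
    list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1])),
    class = "spastr_linear"
  )
}

#' @export
predict.spastr_linear <- function(object, newdata, ...) {
  object$intercept + object$slope * as.numeric(newdata)
}

#' Multivariate linear calibration
#'
#' Ordinary least squares of numeric MAS labels on several biomarkers (the
#' four kinematic biomarkers in the kinematic method). The design matrix must
#' have more rows than columns and full column rank; rank deficiency is
#' reported with the offending columns named.
#'
#' @param x Data frame or matrix of features.
#' @param y Numeric labels.
#' @return A `spastr_mlr` object with `coefficients` (named, per column) and
#'   `intercept`.
#' @export
fit_multilinear <- function(x, y) {
  X <- as.matrix(x)
  stopifnot(is.numeric(y), nrow(X) == length(y))
  if (nrow(X) <= ncol(X)) {
    abort("need more observations than features",
          class = "spastr_calibrate_error")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):ncol(Xd)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(dropped, collapse = ", ")),
          class = "spastr_calibrate_error")
  }
  beta <- qr.coef(qrX, y)
  structure(
    list(coefficients = beta[-1], intercept = unname(beta[1]),
         feature_names = colnames(X)),
    class = "spastr_mlr"
  )
}

#' @export
predict.spastr_mlr <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names) && !is.null(colnames(X))) {
    X <- X[, object$feature_names, drop = FALSE]
  }
  as.numeric(X %*% object$coefficients) + object$intercept
}

#' Mean square error between scores and labels
#'
#' `MSE = mean((label - score)^2)`. This is the headline performance metric
#' of the evaluation harness: the average squared deviation of the continuous
#' evaluation scores from the numeric clinical MAS grades.
#'
#' @param scores Numeric predicted scores.
#' @param labels Numeric labels of the same length (>= 1).
#' @return A single non-negative number.
#' @export
#' @examples
#' mse_score(c(0, 2), c(1, 1)) # 1
mse_score <- function(scores, labels) {
  if (length(scores) != length(labels) || length(scores) < 1) {
    abort("scores and labels must have equal length >= 1",
          class = "spastr_calibrate_error")
  }
  mean((labels - scores)^2)
}
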