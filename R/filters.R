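# Zero-phase Butterworth filtering.
#
# signal::filtfilt() does no edge padding, so transients at both ends leak
# into short biosignal records. The wrapper below reflects the signal about
# its end points (odd reflection, 3x the filter length) before the
# forward-backward pass and trims afterwards, which is the behaviour users of
# scipy/Matlab filtfilt expect.

zero_phase_filter <- function(filt, x) {
  b <- as.numeric(filt$b)
  a <- as.numeric(filt$a)
  nmin <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= nmin) {
    abort(
      paste0("signal too short for zero-phase filtering: need more than ",
             nmin, " samples, got ", n),
      class = "spastr_filter_error"
    )
  }
  # the reflection pad must outlast the filter's own transient, which decays
  # like the largest pole radius; size it so the residual is ~1e-9
  r <- suppressWarnings(max(Mod(polyroot(rev(a)))))
  npad <- nmin
  if (is.finite(r) && r > 0 && r < 1) {
    npad <- max(nmin, ceiling(log(1e-9) / log(r)))
  }
  npad <- min(npad, n - 1L)
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(npad + 1L):(npad + n)]
}

#' Band-pass filter a surface EMG record
#'
#' Applies a zero-phase (forward-backward) fourth-order Butterworth band-pass
#' filter, 20-450 Hz by default, the standard surface-EMG conditioning band.
#' The forward-backward pass doubles the magnitude response and cancels the
#' phase, so symmetric waveforms keep their peak sample.
#'
#' @param x Numeric vector, raw EMG samples.
#' @param fs Sampling rate in Hz (default 1000).
#' @param band Length-2 numeric, pass band in Hz.
#' @param order Butterworth design order (default 4).
#' @return Numeric vector of the same length as `x`.
#' @export
#' @examples
#' filter_emg(sin(2 * pi * 100 * seq(0, 0.5, by = 1e-3)))
filter_emg <- function(x, fs = 1000, band = c(20, 450), order = 4) {
  stopifnot(is.numeric(x), length(band) == 2, band[1] > 0, band[2] < fs / 2)
  filt <- signal::butter(order, band / (fs / 2), type = "pass")
  zero_phase_filter(filt, x)
}

#' Low-pass filter a 3-axis gyroscope record
#'
#' Applies a zero-phase second-order Butterworth low-pass filter (10 Hz by
#' default) independently to each axis. Voluntary/passive elbow motion lives
#' well below 10 Hz; the filter removes sensor noise before the angular-speed
#' magnitude is formed.
#'
#' @param gyro A tibble/data frame with columns `gx`, `gy`, `gz`, or a
#'   numeric matrix with 3 columns (deg/s), or a single numeric vector.
#' @param fs Sampling rate in Hz (default 100).
#' @param cutoff Low-pass corner in Hz.
#' @param order Butterworth design order (default 2).
#' @return An object of the same shape as the input.
#' @export
filter_gyro <- function(gyro, fs = 100, cutoff = 10, order = 2) {
  filt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.numeric(gyro) && is.null(dim(gyro))) {
    return(zero_phase_filter(filt, gyro))
  }
  if (is.matrix(gyro)) {
    return(apply(gyro, 2, function(col) zero_phase_filter(filt, col)))
  }
  stopifnot(all(c("gx", "gy", "gz") %in% names(gyro)))
  out <- gyro
  for (ax in c("gx", "gy", "gz")) {
    out[[ax]] <- zero_phase_filter(filt, gyro[[ax]])
  }
  out
}

#' Moving-RMS detection envelope of an EMG record
#'
#' Full-wave rectification followed by a centred moving RMS (50 ms window by
#' default). The centred window keeps the envelope zero-lag, at the cost of a
#' detection bias bounded by half the window length.
#'
#' @param x Numeric vector (typically band-passed EMG).
#' @param fs Sampling rate in Hz.
#' @param window_s RMS window length in seconds.
#' @return Numeric vector of the same length as `x`.
#' @export
emg_envelope <- function(x, fs = 1000, window_s = 0.05) {
  w <- max(3L, round(window_s * fs))
  if (w %% 2L == 0L) w <- w + 1L
  ms <- as.numeric(stats::filter(x^2, rep(1 / w, w), sides = 2))
  # fill the (w-1)/2 NA samples at either end with the nearest valid value
  half <- (w - 1L) %/% 2L
  n <- length(ms)
  ms[seq_len(half)] <- ms[half + 1L]
  ms[(n - half + 1L):n] <- ms[n - half]
  sqrt(pmax(ms, 0))
}

#' Angular-speed magnitude of a 3-axis gyroscope record
#'
#' Per-sample Euclidean norm of the three gyroscope axes, i.e. the magnitude
#' of the angular velocity vector in deg/s. Direction is discarded, so flexion
#' and extension stretches are treated identically downstream.
#'
#' @param gyro A tibble/data frame with columns `gx`, `gy`, `gz` or a numeric
#'   matrix with 3 columns.
#' @return Non-negative numeric vector.
#' @export
#' @examples
#' angular_speed(data.frame(gx = 3, gy = 4, gz = 0)) # 5
angular_speed <- function(gyro) {
  if (is.matrix(gyro)) {
    stopifnot(ncol(gyro) == 3)
    return(sqrt(rowSums(gyro^2)))
  }
  stopifnot(all(c("gx", "gy", "gz") %in% names(gyro)))
  sqrt(gyro$gx^2 + gyro$gy^2 + gyro$gz^2)
}
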