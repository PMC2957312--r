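#' Acceleration trace from a tremor-sensitive stylus
#'
#' Container for a uniformly sampled scalar acceleration signal (m/s^2).
#' A biaxial stylus records two perpendicular acceleration components; all
#' scalar tremor metrics are computed from the per-sample Euclidean norm of
#' the two axes, which [accel_trace()] forms when `ay` is supplied.
#'
#' @param samples Acceleration values in m/s^2 (single axis or pre-combined
#'   magnitude).
#' @param fs Sampling rate, Hz. Must exceed 30 Hz so the 15 Hz band edge is
#'   resolvable.
#' @param label Free-text task tag, e.g. `"rest"` or `"postural"`.
#' @param ay Optional second perpendicular axis; when given, `samples` is
#'   taken as the first axis and the per-sample norm
#'   `sqrt(ax^2 + ay^2)` is stored.
#' @return An object of class `accel_trace` with fields `samples`, `fs`,
#'   `duration` (s) and `label`.
#' @examples
#' t <- seq(0, 8.192 - 1 / 125, by = 1 / 125)
#' tr <- accel_trace(sin(2 * pi * 5 * t), fs = 125)
#' tr$duration
#' @export
accel_trace <- function(samples, fs, label = "rest", ay = NULL) {
  if (!is.null(ay)) {
    if (length(ay) != length(samples)) {
      stop_argument("biaxial input requires equally long axis vectors")
    }
    samples <- sqrt(samples^2 + ay^2)
  }
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 30) {
    stop_argument("fs must be a single value > 30 Hz (2 x 15 Hz band edge)")
  }
  if (length(samples) < 2 || anyNA(samples)) {
    stop_argument("samples must be a numeric vector without NA")
  }
  structure(
    list(samples = samples, fs = fs, duration = length(samples) / fs,
         label = label),
    class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("<accel_trace> %s: %.3f s at %g Hz (%d samples)\n",
              x$label, x$duration, x$fs, length(x$samples)))
  invisible(x)
}

is_accel_trace <- function(x) inherits(x, "accel_trace")

assert_trace <- function(trace) {
  if (!is_accel_trace(trace)) stop_argument("expected an accel_trace object")
  invisible(trace)
}
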