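#' Tremor spectral metrics
#'
#' The tremor module quantifies a stylus acceleration trace by four scalar
#' metrics computed on the 0.9--15.0 Hz band of its power spectrum:
#'
#' * **TI** (tremor intensity): RMS of the band-pass-filtered acceleration,
#'   m/s^2;
#' * **F50** (center frequency): median frequency of the band-restricted
#'   power distribution, Hz;
#' * **SF50** (frequency dispersion): SD of per-window F50 estimates, Hz;
#' * **HI** (harmonic index): fraction of band power in the dominant
#'   spectral lobe, 1.0 for a single harmonic oscillation.
#'
#' @name tremor-metrics
NULL

## Welch-averaged one-sided power spectrum, rescaled so that
## sum(power) == mean(x^2) exactly (segment windowing slightly
## under-weights the trace edges; the final rescaling restores exact
## Parseval consistency without changing the spectral shape).
welch_psd <- function(x, fs, nseg = 256, overlap = 0.5) {
  n <- length(x)
  if (n < nseg) {
    stop_degenerate(sprintf(
      "trace of %d samples shorter than one %d-sample spectral segment",
      n, nseg))
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1)) # Hann
  scale <- nseg * sum(w^2)
  nfreq <- nseg %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    X <- stats::fft(x[s:(s + nseg - 1L)] * w)
    pk <- Mod(X[1:nfreq])^2 / scale
    pk[2:(nfreq - 1L)] <- 2 * pk[2:(nfreq - 1L)] # fold negative freqs
    acc <- acc + pk
  }
  p <- acc / length(starts)
  if (sum(p) > 0) p <- p * mean(x^2) / sum(p)
  list(freqs = (0:(nfreq - 1L)) * fs / nseg, power = p, df = fs / nseg)
}

#' Band-restricted power spectrum of an acceleration trace
#'
#' Welch-averaged spectrum (Hann window, 256-sample segments, 50% overlap)
#' restricted to the analysis band. Power is scaled so the sum over the
#' full spectrum equals the mean square of the signal (Parseval
#' consistency); restriction keeps only bins whose centers lie in the band.
#'
#' @param trace An [accel_trace()].
#' @param band Analysis band `(f_lo, f_hi)` in Hz; default 0.9--15.0.
#' @param nseg Welch segment length in samples.
#' @return Object of class `tremor_spectrum`: `freqs` (bin centers, Hz),
#'   `power` (nonnegative), `band`, `df` (bin width, Hz).
#' @export
band_spectrum <- function(trace, band = c(0.9, 15.0), nseg = 256) {
  assert_trace(trace)
  if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
      band[2] >= trace$fs / 2) {
    stop_argument("band must be within (0, fs/2) with f_lo < f_hi")
  }
  ps <- welch_psd(trace$samples, trace$fs, nseg = nseg)
  keep <- ps$freqs >= band[1] & ps$freqs <= band[2]
  if (!any(keep)) stop_argument("band contains no spectral bins")
  structure(
    list(freqs = ps$freqs[keep], power = ps$power[keep],
         band = band, df = ps$df),
    class = "tremor_spectrum")
}

#' Tremor intensity (band-limited RMS acceleration)
#'
#' RMS of the acceleration after zero-phase Butterworth band-pass
#' filtering, with `trim` seconds removed from each end so filter
#' transients do not bias the estimate.
#'
#' @inheritParams band_spectrum
#' @param trim Seconds trimmed from each end after filtering (default 0.5).
#' @return TI in m/s^2 (nonnegative scalar).
#' @export
tremor_intensity <- function(trace, band = c(0.9, 15.0), trim = 0.5) {
  assert_trace(trace)
  y <- bandpass_zerophase(trace$samples, trace$fs, band)
  y <- trim_edges(y, round(trim * trace$fs))
  sqrt(mean(y^2))
}

#' Center frequency (F50) of a band-restricted spectrum
#'
#' Median of the power distribution over frequency: the smallest frequency
#' at which cumulative band power reaches 50% of the total, linearly
#' interpolated inside the crossing bin (bin mass treated as uniform over
#' the bin width), which removes bin-width quantization.
#'
#' @param spec A `tremor_spectrum` from [band_spectrum()].
#' @return F50 in Hz.
#' @export
center_frequency <- function(spec) {
  stopifnot(inherits(spec, "tremor_spectrum"))
  tot <- sum(spec$power)
  if (tot <= 0) stop_degenerate("zero total band power; F50 undefined")
  cum <- cumsum(spec$power)
  i <- which(cum >= tot / 2)[1]
  prev <- if (i > 1) cum[i - 1] else 0
  lo_edge <- spec$freqs[i] - spec$df / 2
  lo_edge + (tot / 2 - prev) / spec$power[i] * spec$df
}

#' Frequency dispersion (SF50)
#'
#' Standard deviation of per-window center-frequency estimates over
#' sliding windows (default 2.048 s, 50% overlap). A constant-frequency
#' signal gives a value near zero; frequency-unstable tremor gives larger
#' values.
#'
#' @inheritParams band_spectrum
#' @param window Window length in seconds.
#' @param overlap Fractional overlap between successive windows.
#' @return SF50 in Hz (sample SD over windows).
#' @export
frequency_dispersion <- function(trace, window = 2.048, overlap = 0.5,
                                 band = c(0.9, 15.0)) {
  assert_trace(trace)
  nwin <- round(window * trace$fs)
  step <- max(1L, round(nwin * (1 - overlap)))
  n <- length(trace$samples)
  starts <- if (n >= nwin) seq(1L, n - nwin + 1L, by = step) else integer(0)
  if (length(starts) < 3) {
    stop_degenerate("trace too short for >= 3 center-frequency windows")
  }
  f50s <- vapply(starts, function(s) {
    seg <- accel_trace(trace$samples[s:(s + nwin - 1L)], trace$fs,
                       label = trace$label)
    center_frequency(band_spectrum(seg, band = band, nseg = nwin))
  }, numeric(1))
  sample_sd(f50s)
}

#' Harmonic index (HI)
#'
#' Concentration of band power consistent with a single harmonic
#' oscillation. The dominant spectral lobe is the global-maximum bin
#' extended to adjacent bins while power is monotonically non-increasing
#' outward; HI is the lobe power divided by total band power. A single
#' spectral line gives 1.0 (to within window leakage); power spread over
#' frequent irregular oscillations drives HI toward 0.
#'
#' @param spec A `tremor_spectrum` from [band_spectrum()].
#' @return HI in \[0, 1\].
#' @export
harmonic_index <- function(spec) {
  stopifnot(inherits(spec, "tremor_spectrum"))
  p <- spec$power
  tot <- sum(p)
  if (tot <= 0) stop_degenerate("zero total band power; HI undefined")
  i <- which.max(p)
  lo <- i
  while (lo > 1 && p[lo - 1] <= p[lo]) lo <- lo - 1
  hi <- i
  while (hi < length(p) && p[hi + 1] <= p[hi]) hi <- hi + 1
  sum(p[lo:hi]) / tot
}

#' All four tremor metrics of a trace
#'
#' Bundles [tremor_intensity()], [center_frequency()],
#' [frequency_dispersion()] and [harmonic_index()] with the default
#' 0.9--15.0 Hz analysis band.
#'
#' @inheritParams band_spectrum
#' @return Object of class `tremor_metrics`: named list with `TI`, `F50`,
#'   `SF50`, `HI`.
#' @examples
#' tr <- simulate_tremor_trace(seed = 1)
#' unlist(tremor_metrics(tr))
#' @export
tremor_metrics <- function(trace, band = c(0.9, 15.0)) {
  assert_trace(trace)
  spec <- band_spectrum(trace, band = band)
  structure(
    list(TI = tremor_intensity(trace, band = band),
         F50 = center_frequency(spec),
         SF50 = frequency_dispersion(trace, band = band),
         HI = harmonic_index(spec)),
    class = "tremor_metrics")
}

#' @export
print.tremor_metrics <- function(x, ...) {
  cat(sprintf("TI %.4f m/s^2 | F50 %.2f Hz | SF50 %.2f Hz | HI %.3f\n",
              x$TI, x$F50, x$SF50, x$HI))
  invisible(x)
}
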