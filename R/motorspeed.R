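#' Tap series from a touch recording plate
#'
#' Ordered plate-contact timestamps over a fixed recording window, from a
#' maximum-frequency pronation/supination or finger-tapping task.
#'
#' @param hit_times Strictly increasing contact times in seconds, all
#'   within `[0, T]`.
#' @param T Recording duration in seconds (> 0).
#' @param task `"pronation_supination"` or `"finger_tapping"`.
#' @param side `"right"`, `"left"`, `"dominant"` or `"nondominant"`.
#' @return Object of class `tap_series`.
#' @export
tap_series <- function(hit_times, T, task = "finger_tapping",
                       side = "right") {
  hit_times <- as.numeric(hit_times)
  if (!is.numeric(T) || length(T) != 1 || T <= 0) {
    stop_argument("T must be a single positive duration in seconds")
  }
  if (length(hit_times) > 0) {
    if (anyNA(hit_times) || any(hit_times < 0) || any(hit_times > T)) {
      stop_argument("hit_times must lie within [0, T]")
    }
    if (is.unsorted(hit_times, strictly = TRUE)) {
      stop_argument("hit_times must be strictly increasing")
    }
  }
  structure(list(hit_times = hit_times, T = T, task = task, side = side),
            class = "tap_series")
}

#' Mean tap frequency (MFT)
#'
#' Total number of plate contacts divided by the recording time.
#'
#' @param taps A [tap_series()].
#' @return MFT in Hz (events/s).
#' @export
mean_tap_frequency <- function(taps) {
  stopifnot(inherits(taps, "tap_series"))
  length(taps$hit_times) / taps$T
}

#' Tap frequency variability (MFT-SD)
#'
#' Sample SD of the instantaneous tap frequencies, i.e. the reciprocals of
#' successive inter-tap intervals. A perfectly periodic tapper scores 0;
#' variable hit speed raises the value.
#'
#' @param taps A [tap_series()] with at least 3 hits.
#' @return MFT-SD in Hz.
#' @export
tap_frequency_sd <- function(taps) {
  stopifnot(inherits(taps, "tap_series"))
  if (length(taps$hit_times) < 3) {
    stop_degenerate("need >= 3 hits for inter-tap frequency variability")
  }
  sample_sd(1 / diff(taps$hit_times))
}

#' Simple reaction-time trial set
#'
#' Stimulus times and response latencies from a reaction-handle session.
#' A missing response (no click before the maximum permitted reaction
#' time) is recorded as `NA`.
#'
#' @param stimulus_times Stimulus onset times in seconds within the
#'   session window.
#' @param raw_rts Response latency in seconds per stimulus, `NA` for
#'   misses. Same length as `stimulus_times`.
#' @param max_rt Maximum permitted reaction time in seconds (> 0.10);
#'   default 2.0 (user-configurable on the original device).
#' @param session_length Session window in seconds; default 40.
#' @return Object of class `reaction_trials`.
#' @export
reaction_trials <- function(stimulus_times, raw_rts, max_rt = 2.0,
                            session_length = 40) {
  if (length(stimulus_times) != length(raw_rts)) {
    stop_argument("stimulus_times and raw_rts must be aligned")
  }
  if (session_length <= 0) stop_argument("session_length must be positive")
  if (max_rt <= 0.10) stop_argument("max_rt must exceed 0.10 s")
  structure(
    list(stimulus_times = as.numeric(stimulus_times),
         raw_rts = as.numeric(raw_rts),
         max_rt = max_rt, session_length = session_length),
    class = "reaction_trials")
}

#' Validity filter for reaction times
#'
#' Retains responses with `0.10 <= rt <= max_rt`: latencies below 0.10 s
#' are anticipatory and invalid, latencies above the maximum permitted
#' reaction time are excluded, and missing responses are dropped. The
#' boundaries themselves are valid (the exclusion rules are strict
#' inequalities). Idempotent.
#'
#' @param trials A [reaction_trials()].
#' @param rt_min Validity floor in seconds, default 0.10.
#' @return A filtered [reaction_trials()] containing only valid trials.
#' @export
filter_reaction_times <- function(trials, rt_min = 0.10) {
  stopifnot(inherits(trials, "reaction_trials"))
  keep <- !is.na(trials$raw_rts) &
    trials$raw_rts >= rt_min & trials$raw_rts <= trials$max_rt
  reaction_trials(trials$stimulus_times[keep], trials$raw_rts[keep],
                  max_rt = trials$max_rt,
                  session_length = trials$session_length)
}

#' Reaction-time metrics (RT, RT-SD)
#'
#' Mean and sample SD of the valid reaction times (validity filter applied
#' internally; already-filtered sets pass through unchanged). With no
#' valid trial both metrics are `NA`; with a single valid trial the mean
#' is defined and the SD is `NA`.
#'
#' @inheritParams filter_reaction_times
#' @return Object of class `motorspeed_metrics`: `RT` (s), `RT_SD` (s),
#'   `n_valid`.
#' @export
reaction_metrics <- function(trials, rt_min = 0.10) {
  valid <- filter_reaction_times(trials, rt_min = rt_min)$raw_rts
  n <- length(valid)
  structure(
    list(RT = if (n >= 1) mean(valid) else NA_real_,
         RT_SD = if (n >= 2) sample_sd(valid) else NA_real_,
         n_valid = n),
    class = "motorspeed_metrics")
}

#' @export
print.motorspeed_metrics <- function(x, ...) {
  cat(sprintf("RT %.3f s | RT-SD %.3f s | n_valid %d\n",
              x$RT, x$RT_SD, x$n_valid))
  invisible(x)
}
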