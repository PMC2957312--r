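#' Standard evaluation protocol
#'
#' The default battery: rest and postural tremor 8.192 s per hand at
#' 125 Hz (displayed as 8.2 s on the original device; 1024 samples),
#' maximum-frequency pronation/supination and finger tapping 10 s per
#' hand, simple reaction time with 9 randomly spaced tones in 40 s per
#' hand, and an 80.5 s stance on the force plate at 50 Hz with a 10 s
#' run-in and 5 s run-out (65.5 s analyzed).
#'
#' @return Data frame with one row per task: `task`, `device`, `duration`
#'   (s), `bilateral`, `fs` (Hz, where fixed-rate), `n_stimuli`,
#'   `run_in`, `run_out`.
#' @export
default_protocol <- function() {
  data.frame(
    task = c("rest_tremor", "postural_tremor", "pronation_supination",
             "finger_tapping", "reaction", "stance"),
    device = c("tremor_pen", "tremor_pen", "touch_plate", "touch_plate",
               "reaction_handle", "force_plate"),
    duration = c(8.192, 8.192, 10, 10, 40, 80.5),
    bilateral = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    fs = c(125, 125, NA, NA, NA, 50),
    n_stimuli = c(NA, NA, NA, NA, 9, NA),
    run_in = c(0, 0, 0, 0, 0, 10),
    run_out = c(0, 0, 0, 0, 0, 5),
    stringsAsFactors = FALSE)
}

#' Total scheduled recording time of a protocol
#'
#' @param protocol A [default_protocol()]-shaped data frame.
#' @return Seconds of recording scheduled (bilateral tasks counted twice).
#' @export
protocol_recording_time <- function(protocol = default_protocol()) {
  sum(protocol$duration * ifelse(protocol$bilateral, 2, 1))
}

#' Per-subject session container
#'
#' Holds every raw task recording of one subject, keyed `"task.side"`
#' (`"stance"` for the unilateral balance task), the group label, and
#' optional clinician-rated item scores (rest-tremor item per side,
#' action/postural-tremor item per side, body-bradykinesia item, each an
#' integer 0--4, plus disease stage).
#'
#' @param subject_id Identifier.
#' @param group `"pd"` or `"control"`.
#' @param recordings Named list of recordings ([accel_trace()],
#'   [tap_series()], [reaction_trials()], [sway_recording()]).
#' @param dominant_side `"right"` or `"left"`.
#' @param clinical Optional list: `updrs20`/`updrs21` (lists with `right`,
#'   `left`), `updrs31`, `hy_stage`.
#' @return Object of class `subject_session`.
#' @export
subject_session <- function(subject_id, group = c("pd", "control"),
                            recordings = list(),
                            dominant_side = "right", clinical = list()) {
  group <- match.arg(group)
  for (nm in c("updrs20", "updrs21")) {
    it <- clinical[[nm]]
    if (!is.null(it)) {
      vals <- unlist(it)
      if (any(!vals %in% 0:4)) {
        stop_validation(sprintf("%s scores must be integers in 0..4", nm))
      }
    }
  }
  if (!is.null(clinical$updrs31) && !clinical$updrs31 %in% 0:4) {
    stop_validation("updrs31 score must be an integer in 0..4")
  }
  structure(
    list(subject_id = subject_id, group = group, recordings = recordings,
         dominant_side = dominant_side, clinical = clinical),
    class = "subject_session")
}

#' @export
print.subject_session <- function(x, ...) {
  cat(sprintf("<subject_session> %s (%s): %d recordings\n",
              x$subject_id, x$group, length(x$recordings)))
  invisible(x)
}

## duration of any recording type, seconds
recording_duration <- function(rec) {
  if (inherits(rec, "accel_trace") || inherits(rec, "sway_recording")) {
    rec$duration
  } else if (inherits(rec, "tap_series")) {
    rec$T
  } else if (inherits(rec, "reaction_trials")) {
    rec$session_length
  } else {
    stop_argument("unknown recording type")
  }
}

## one-sample duration tolerance at the recording's own rate (event-based
## recordings get 0.1 s)
duration_tol <- function(rec) {
  if (inherits(rec, "accel_trace") || inherits(rec, "sway_recording")) {
    1 / rec$fs + 1e-9
  } else {
    0.1
  }
}

upper_metric_names <- function() {
  c(paste0("rest_tremor_", c("TI", "F50", "SF50", "HI")),
    paste0("postural_tremor_", c("TI", "F50", "SF50", "HI")),
    paste0("pronation_supination_", c("MFT", "MFT_SD")),
    paste0("finger_tapping_", c("MFT", "MFT_SD")),
    "reaction_RT", "reaction_RT_SD")
}

sway_metric_names <- function() c("TS", "SS", "MS", "SA", "SV", "SI")

#' Run the battery on one subject session
#'
#' Computes every metric for every task recording present in the session,
#' validating each recording's duration against the protocol (tolerance:
#' one sample at the recording's rate). Missing recordings yield `NA`
#' metrics, never imputed values. Deterministic given the recordings, and
#' independent of task order.
#'
#' @param session A [subject_session()].
#' @param protocol A [default_protocol()]-shaped data frame.
#' @return One-row data frame: `subject_id`, `group`, `dominant_side`,
#'   clinical items, then `<task>_<side>_<metric>` for the bilateral tasks
#'   and `stance_<metric>` for sway.
#' @export
run_session <- function(session, protocol = default_protocol()) {
  stopifnot(inherits(session, "subject_session"))
  out <- list(subject_id = session$subject_id, group = session$group,
              dominant_side = session$dominant_side)
  cl <- session$clinical
  out$updrs20_right <- cl$updrs20$right %||% NA_integer_
  out$updrs20_left <- cl$updrs20$left %||% NA_integer_
  out$updrs21_right <- cl$updrs21$right %||% NA_integer_
  out$updrs21_left <- cl$updrs21$left %||% NA_integer_
  out$updrs31 <- cl$updrs31 %||% NA_integer_
  out$hy_stage <- cl$hy_stage %||% NA_real_

  fetch <- function(key, expected_dur) {
    rec <- session$recordings[[key]]
    if (is.null(rec)) return(NULL)
    dur <- recording_duration(rec)
    if (abs(dur - expected_dur) > duration_tol(rec)) {
      stop_validation(sprintf(
        "recording '%s': duration %.4f s does not match protocol %.4f s",
        key, dur, expected_dur))
    }
    rec
  }

  for (i in seq_len(nrow(protocol))) {
    pr <- protocol[i, ]
    if (pr$device == "tremor_pen") {
      for (sd_ in c("right", "left")) {
        rec <- fetch(paste(pr$task, sd_, sep = "."), pr$duration)
        m <- if (is.null(rec)) {
          list(TI = NA_real_, F50 = NA_real_, SF50 = NA_real_,
               HI = NA_real_)
        } else tremor_metrics(rec)
        for (nm in c("TI", "F50", "SF50", "HI")) {
          out[[paste(pr$task, sd_, nm, sep = "_")]] <- m[[nm]]
        }
      }
    } else if (pr$device == "touch_plate") {
      for (sd_ in c("right", "left")) {
        rec <- fetch(paste(pr$task, sd_, sep = "."), pr$duration)
        out[[paste(pr$task, sd_, "MFT", sep = "_")]] <-
          if (is.null(rec)) NA_real_ else mean_tap_frequency(rec)
        out[[paste(pr$task, sd_, "MFT_SD", sep = "_")]] <-
          if (is.null(rec) || length(rec$hit_times) < 3) NA_real_
          else tap_frequency_sd(rec)
      }
    } else if (pr$device == "reaction_handle") {
      for (sd_ in c("right", "left")) {
        rec <- fetch(paste(pr$task, sd_, sep = "."), pr$duration)
        m <- if (is.null(rec)) {
          list(RT = NA_real_, RT_SD = NA_real_, n_valid = NA_integer_)
        } else reaction_metrics(rec)
        out[[paste(pr$task, sd_, "RT", sep = "_")]] <- m$RT
        out[[paste(pr$task, sd_, "RT_SD", sep = "_")]] <- m$RT_SD
        out[[paste(pr$task, sd_, "n_valid", sep = "_")]] <- m$n_valid
      }
    } else if (pr$device == "force_plate") {
      rec <- fetch(pr$task, pr$duration)
      m <- if (is.null(rec)) {
        as.list(stats::setNames(rep(NA_real_, 6), sway_metric_names()))
      } else sway_metrics(rec, run_in = pr$run_in, run_out = pr$run_out)
      for (nm in sway_metric_names()) {
        out[[paste(pr$task, nm, sep = "_")]] <- m[[nm]]
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Run the battery on a whole cohort
#'
#' @param sessions List of [subject_session()] (e.g. from
#'   [simulate_cohort()]).
#' @inheritParams run_session
#' @return Data frame, one row per subject ([run_session()] rows bound
#'   together).
#' @export
cohort_metrics <- function(sessions, protocol = default_protocol()) {
  do.call(rbind, lapply(sessions, run_session, protocol = protocol))
}
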