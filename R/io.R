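#' File formats
#'
#' All time series are delimited text with decimal seconds. Metadata that
#' a binary device format would carry (task, side, window length, sensor
#' coordinates) travels in `#`-prefixed key=value header lines above the
#' CSV header, so each recording file is self-describing.
#'
#' @name neurocat-io
NULL

## "# key=value key=value" header lines -> named character vector
read_header_meta <- function(path) {
  lines <- readLines(path, n = 10)
  meta <- character(0)
  for (ln in lines[startsWith(lines, "#")]) {
    kv <- regmatches(ln, gregexpr("[A-Za-z_0-9]+=[^ ]+", ln))[[1]]
    for (p in kv) {
      eq <- regexpr("=", p)
      meta[substr(p, 1, eq - 1)] <- substr(p, eq + 1, nchar(p))
    }
  }
  meta
}

meta_get <- function(meta, key, default = NA_character_) {
  v <- unname(meta[key])
  if (length(v) != 1 || is.na(v)) default else v
}

write_with_meta <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", paste(names(meta), unname(meta), sep = "=",
                              collapse = " ")), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

check_columns <- function(df, needed, path, alternatives = NULL) {
  if (all(needed %in% names(df))) return(needed)
  if (!is.null(alternatives) && all(alternatives %in% names(df))) {
    return(alternatives)
  }
  stop_data(sprintf("%s: expected columns %s, found %s", path,
                    paste(needed, collapse = ","),
                    paste(names(df), collapse = ",")))
}

## uniform-sampling check on a time column: max deviation from the median
## step must stay below half a sample period
check_uniform_time <- function(t, path) {
  if (anyNA(t) || !is.numeric(t)) {
    stop_data(sprintf("%s: non-numeric or missing timestamps", path))
  }
  dt <- diff(t)
  if (any(dt <= 0)) {
    stop_data(sprintf("%s: non-monotone timestamps starting at row %d",
                      path, which(dt <= 0)[1] + 1L))
  }
  step <- stats::median(dt)
  bad <- which(abs(dt - step) > step / 2)
  if (length(bad) > 0) {
    stop_data(sprintf(
      "%s: non-uniform sampling near t = %.4f s (gap %.4f s vs period %.4f s)",
      path, t[bad[1]], dt[bad[1]], step))
  }
  1 / step
}

#' Read an acceleration trace CSV
#'
#' Columns `t,ax,ay` (biaxial; combined by Euclidean norm) or `t,a`
#' (pre-combined magnitude). Sampling uniformity is validated from `t`.
#'
#' @param path CSV path.
#' @param label Task tag; defaults to the file's `task` header field.
#' @return An [accel_trace()].
#' @export
read_accel_csv <- function(path, label = NULL) {
  meta <- read_header_meta(path)
  df <- read.csv(path, comment.char = "#")
  cols <- check_columns(df, c("t", "ax", "ay"), path,
                        alternatives = c("t", "a"))
  fs <- check_uniform_time(df$t, path)
  label <- label %||% meta_get(meta, "task", "rest")
  if (length(cols) == 3) {
    accel_trace(df$ax, fs, label = label, ay = df$ay)
  } else {
    accel_trace(df$a, fs, label = label)
  }
}

#' @rdname read_accel_csv
#' @param trace An [accel_trace()] to write.
#' @export
write_accel_csv <- function(trace, path) {
  write_with_meta(
    data.frame(t = (seq_along(trace$samples) - 1) / trace$fs,
               a = trace$samples),
    path, c(task = trace$label, fs = format(trace$fs)))
  invisible(path)
}

#' Read / write a tap-series CSV
#'
#' Single `hit_time` column; recording duration, task and side travel in
#' the `#` metadata header.
#'
#' @param path CSV path.
#' @return A [tap_series()].
#' @export
read_taps_csv <- function(path) {
  meta <- read_header_meta(path)
  if (is.na(meta["duration"])) {
    stop_data(sprintf("%s: missing duration metadata", path))
  }
  df <- read.csv(path, comment.char = "#")
  check_columns(df, "hit_time", path)
  tap_series(df$hit_time, T = as.numeric(meta[["duration"]]),
             task = meta_get(meta, "task", "finger_tapping"),
             side = meta_get(meta, "side", "right"))
}

#' @rdname read_taps_csv
#' @param taps A [tap_series()] to write.
#' @export
write_taps_csv <- function(taps, path) {
  write_with_meta(data.frame(hit_time = taps$hit_times), path,
                  c(duration = format(taps$T), task = taps$task,
                    side = taps$side))
  invisible(path)
}

#' Read / write a reaction-trial CSV
#'
#' Columns `stimulus_time,rt` with empty `rt` for misses; `max_rt` and
#' the session length travel in the metadata header.
#'
#' @param path CSV path.
#' @param max_rt Override for the maximum permitted reaction time.
#' @return A [reaction_trials()].
#' @export
read_reaction_csv <- function(path, max_rt = NULL) {
  meta <- read_header_meta(path)
  df <- read.csv(path, comment.char = "#")
  check_columns(df, c("stimulus_time", "rt"), path)
  reaction_trials(
    df$stimulus_time, df$rt,
    max_rt = max_rt %||% as.numeric(meta_get(meta, "max_rt", "2")),
    session_length = as.numeric(meta_get(meta, "session_length", "40")))
}

#' @rdname read_reaction_csv
#' @param trials A [reaction_trials()] to write.
#' @export
write_reaction_csv <- function(trials, path) {
  write_with_meta(
    data.frame(stimulus_time = trials$stimulus_times, rt = trials$raw_rts),
    path, c(max_rt = format(trials$max_rt),
            session_length = format(trials$session_length)))
  invisible(path)
}

#' Read / write a force-plate CSV
#'
#' Columns `t,f1,f2,f3`; sensor coordinates travel in the metadata header
#' as `sensors=x1:y1;x2:y2;x3:y3` (mm).
#'
#' @param path CSV path.
#' @return A [sway_recording()].
#' @export
read_forces_csv <- function(path) {
  meta <- read_header_meta(path)
  df <- read.csv(path, comment.char = "#")
  check_columns(df, c("t", "f1", "f2", "f3"), path)
  fs <- check_uniform_time(df$t, path)
  sensor_xy <- if (!is.na(meta["sensors"])) {
    pts <- strsplit(strsplit(meta[["sensors"]], ";")[[1]], ":")
    do.call(rbind, lapply(pts, as.numeric))
  } else default_sensor_geometry()
  sway_recording(cbind(df$f1, df$f2, df$f3), fs, sensor_xy)
}

#' @rdname read_forces_csv
#' @param rec A [sway_recording()] to write.
#' @export
write_forces_csv <- function(rec, path) {
  sensors <- paste(apply(rec$sensor_xy, 1,
                         function(r) paste(r, collapse = ":")),
                   collapse = ";")
  write_with_meta(
    data.frame(t = (seq_len(nrow(rec$forces)) - 1) / rec$fs,
               f1 = rec$forces[, 1], f2 = rec$forces[, 2],
               f3 = rec$forces[, 3]),
    path, c(fs = format(rec$fs), sensors = sensors))
  invisible(path)
}

#' Write / read a cohort metric table
#'
#' Deterministic column order, empty cells for missing metrics; a
#' round-trip read returns values equal to 1e-9.
#'
#' @param tbl Metric table ([cohort_metrics()] or
#'   [reduce_most_affected()] output).
#' @param path CSV path.
#' @export
write_metrics_csv <- function(tbl, path) {
  write.csv(tbl[, sort(names(tbl))], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  # all-missing metric columns come back logical; they are numeric nulls
  for (nm in names(df)) {
    if (is.logical(df[[nm]]) && all(is.na(df[[nm]]))) {
      df[[nm]] <- as.numeric(df[[nm]])
    }
  }
  df
}

# ---------------------------------------------------------------------------
# session manifests

manifest_schema_fields <- function() {
  c("schema_version", "subject_id", "group", "dominant_side", "clinical",
    "recordings")
}

#' Save a subject session to disk
#'
#' Writes every recording as CSV plus a versioned `manifest.json` listing
#' subject metadata, clinical items and relative recording paths.
#'
#' @param session A [subject_session()].
#' @param dir Output directory (created if needed).
#' @return Path of the manifest file.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (key in names(session$recordings)) {
    rec <- session$recordings[[key]]
    fn <- paste0(gsub("[^A-Za-z0-9_.]", "_", key), ".csv")
    fp <- file.path(dir, fn)
    if (inherits(rec, "accel_trace")) write_accel_csv(rec, fp)
    else if (inherits(rec, "tap_series")) write_taps_csv(rec, fp)
    else if (inherits(rec, "reaction_trials")) write_reaction_csv(rec, fp)
    else if (inherits(rec, "sway_recording")) write_forces_csv(rec, fp)
    else stop_argument(sprintf("unknown recording type for '%s'", key))
    paths[[key]] <- fn
  }
  manifest <- list(schema_version = 1L,
                   subject_id = session$subject_id,
                   group = session$group,
                   dominant_side = session$dominant_side,
                   clinical = session$clinical,
                   recordings = paths)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mf)
}

#' Validate a parsed session manifest
#'
#' Schema version must be 1; unknown top-level fields are rejected (not
#' ignored) to catch task-name and key typos early.
#'
#' @param manifest Parsed manifest list.
#' @return The manifest, invisibly, if valid.
#' @export
validate_manifest <- function(manifest) {
  unknown <- setdiff(names(manifest), manifest_schema_fields())
  if (length(unknown) > 0) {
    stop_validation(sprintf("unknown manifest fields: %s",
                            paste(unknown, collapse = ", ")))
  }
  required <- c("schema_version", "subject_id", "group", "recordings")
  missing <- setdiff(required, names(manifest))
  if (length(missing) > 0) {
    stop_validation(sprintf("manifest missing fields: %s",
                            paste(missing, collapse = ", ")))
  }
  if (!identical(as.integer(manifest$schema_version), 1L)) {
    stop_validation("unsupported manifest schema_version")
  }
  if (!manifest$group %in% c("pd", "control")) {
    stop_validation("manifest group must be 'pd' or 'control'")
  }
  known_tasks <- default_protocol()$task
  for (key in names(manifest$recordings)) {
    task <- sub("\\..*$", "", key)
    if (!task %in% known_tasks) {
      stop_validation(sprintf("unknown task '%s' in manifest", task))
    }
  }
  invisible(manifest)
}

#' Load a subject session from a manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_session()].
#' @return A [subject_session()].
#' @export
read_session <- function(manifest_path) {
  manifest <- jsonlite::read_json(manifest_path)
  validate_manifest(manifest)
  base <- dirname(manifest_path)
  rec <- list()
  for (key in names(manifest$recordings)) {
    fp <- file.path(base, manifest$recordings[[key]])
    task <- sub("\\..*$", "", key)
    device <- default_protocol()$device[default_protocol()$task == task]
    rec[[key]] <- switch(device,
      tremor_pen = read_accel_csv(fp),
      touch_plate = read_taps_csv(fp),
      reaction_handle = read_reaction_csv(fp),
      force_plate = read_forces_csv(fp))
  }
  clinical <- manifest$clinical %||% list()
  subject_session(manifest$subject_id, manifest$group, recordings = rec,
                  dominant_side = manifest$dominant_side %||% "right",
                  clinical = clinical)
}

#' Save a whole cohort
#'
#' One sub-directory per subject plus a cohort index JSON recording the
#' seed and per-subject manifest paths.
#'
#' @param sessions Cohort list from [simulate_cohort()].
#' @param dir Output directory.
#' @return Path of the cohort index file.
#' @export
write_cohort <- function(sessions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(sessions, function(s) {
    write_session(s, file.path(dir, s$subject_id))
    list(subject_id = s$subject_id, group = s$group,
         manifest = file.path(s$subject_id, "manifest.json"))
  })
  idx <- file.path(dir, "cohort.json")
  jsonlite::write_json(
    list(schema_version = 1L, seed = attr(sessions, "seed"),
         subjects = entries),
    idx, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(idx)
}

#' @rdname write_cohort
#' @param index_path Path to a `cohort.json`.
#' @export
read_cohort <- function(index_path) {
  idx <- jsonlite::read_json(index_path)
  base <- dirname(index_path)
  sessions <- lapply(idx$subjects, function(e) {
    read_session(file.path(base, e$manifest))
  })
  structure(sessions, seed = idx$seed)
}
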