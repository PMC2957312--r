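#' Default force-plate sensor geometry
#'
#' Three vertical-force sensors at the corners of a triangle inscribed in
#' the 40 cm x 29 cm plate (plate centered at the origin, x transversal,
#' y sagittal, mm). The true sensor placement of the commercial plate is
#' unpublished; metrics depend only on force ratios and COP position, so
#' any non-collinear placement spanning the stance area works.
#'
#' @return 3 x 2 matrix of sensor coordinates in mm.
#' @export
default_sensor_geometry <- function() {
  rbind(c(-160, -120), c(160, -120), c(0, 120))
}

#' Static-posturography recording
#'
#' Three-channel vertical-force time series from a rectangular force
#' plate. Forces are recorded at three non-collinear points; the
#' force-weighted centroid of the sensor positions gives the center of
#' force (COP). Force units cancel in the COP computation, so
#' kilogram-equivalent readings are accepted as recorded.
#'
#' @param forces n x 3 matrix of nonnegative vertical forces, uniformly
#'   sampled.
#' @param fs Sampling rate, Hz.
#' @param sensor_xy 3 x 2 matrix of sensor positions in plate coordinates
#'   (mm); default [default_sensor_geometry()].
#' @return Object of class `sway_recording` with fields `forces`, `fs`,
#'   `duration`, `sensor_xy`.
#' @export
sway_recording <- function(forces, fs, sensor_xy = default_sensor_geometry()) {
  forces <- as.matrix(forces)
  if (ncol(forces) != 3 || nrow(forces) < 2) {
    stop_argument("forces must be an n x 3 matrix with n >= 2")
  }
  if (anyNA(forces) || any(forces < 0)) {
    stop_argument("forces must be nonnegative and complete")
  }
  sensor_xy <- as.matrix(sensor_xy)
  if (!all(dim(sensor_xy) == c(3, 2))) {
    stop_argument("sensor_xy must be a 3 x 2 coordinate matrix")
  }
  # non-collinearity: triangle area must be positive
  tri <- abs((sensor_xy[2, 1] - sensor_xy[1, 1]) *
               (sensor_xy[3, 2] - sensor_xy[1, 2]) -
             (sensor_xy[3, 1] - sensor_xy[1, 1]) *
               (sensor_xy[2, 2] - sensor_xy[1, 2])) / 2
  if (tri <= 0) stop_argument("sensor positions must be non-collinear")
  if (fs <= 0) stop_argument("fs must be positive")
  structure(
    list(forces = forces, fs = fs, duration = nrow(forces) / fs,
         sensor_xy = sensor_xy),
    class = "sway_recording")
}

#' Center-of-force trajectory
#'
#' Per-sample COP as the force-weighted centroid of the three sensor
#' positions, then mean-centered so the mean force-center position is the
#' coordinate origin.
#'
#' @param rec A [sway_recording()].
#' @return Object of class `cop_trajectory`: `xy` (n x 2, mm, centered),
#'   `fs`, `center` (the removed mean position in plate coordinates).
#' @export
center_of_force <- function(rec) {
  stopifnot(inherits(rec, "sway_recording"))
  tot <- rowSums(rec$forces)
  if (any(tot <= 0)) {
    stop_data(sprintf("zero total force at sample %s; COP undefined",
                      which(tot <= 0)[1]))
  }
  xy <- (rec$forces %*% rec$sensor_xy) / tot
  ctr <- colMeans(xy)
  cop_trajectory(sweep(xy, 2, ctr), rec$fs, center = ctr)
}

#' Centered COP trajectory container
#'
#' @param xy n x 2 matrix of COP coordinates in mm, mean-centered.
#' @param fs Sampling rate, Hz.
#' @param center Optional original mean position (plate coordinates).
#' @param recenter Recenter `xy` on construction (default TRUE).
#' @return Object of class `cop_trajectory`.
#' @export
cop_trajectory <- function(xy, fs, center = c(0, 0), recenter = TRUE) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2 || anyNA(xy) || any(!is.finite(xy))) {
    stop_argument("xy must be a finite n x 2 matrix")
  }
  if (recenter) {
    m <- colMeans(xy)
    xy <- sweep(xy, 2, m)
    center <- center + m
  }
  structure(list(xy = xy, fs = fs, center = center),
            class = "cop_trajectory")
}

#' Transversal and sagittal sway (TS, SS)
#'
#' Mean absolute deviation of the centered COP along the transversal (x)
#' and sagittal (y) axes. (The signed mean is identically zero after
#' centering; the mean absolute excursion is the sway amplitude.)
#'
#' @param traj A [cop_trajectory()].
#' @return Named numeric vector `c(TS =, SS =)` in mm.
#' @export
axis_sway <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  c(TS = mean(abs(traj$xy[, 1])), SS = mean(abs(traj$xy[, 2])))
}

#' Mean sway (MS)
#'
#' Mean Euclidean distance from the mean force-center position to all
#' recorded positions.
#'
#' @inheritParams axis_sway
#' @return MS in mm.
#' @export
mean_sway <- function(traj) {
  stopifnot(inherits(traj, "cop_trajectory"))
  mean(sqrt(rowSums(traj$xy^2)))
}

#' Sway area (SA)
#'
#' Area of the smallest convex polygon containing the whole COP
#' trajectory (convex hull, shoelace area). `mode = "grid"` instead counts
#' 1 mm (or `cell` mm) grid cells visited by the trajectory samples and
#' reports occupied-cell count times cell area, an alternative
#' grid-occupancy reading of the same quantity.
#'
#' @inheritParams axis_sway
#' @param mode `"hull"` (default) or `"grid"`.
#' @param cell Grid cell edge in mm (grid mode only).
#' @return SA in mm^2. Fewer than 3 distinct points, or a collinear
#'   trajectory, gives 0 with a warning (hull mode).
#' @export
sway_area <- function(traj, mode = c("hull", "grid"), cell = 1) {
  stopifnot(inherits(traj, "cop_trajectory"))
  mode <- match.arg(mode)
  xy <- traj$xy
  if (mode == "grid") {
    cells <- unique(paste(floor(xy[, 1] / cell), floor(xy[, 2] / cell)))
    return(length(cells) * cell^2)
  }
  if (nrow(unique(xy)) < 3) {
    warning("fewer than 3 distinct COP points; sway area is 0")
    return(0)
  }
  h <- grDevices::chull(xy)
  if (length(h) < 3) {
    warning("collinear COP trajectory; sway area is 0")
    return(0)
  }
  x <- xy[h, 1]; y <- xy[h, 2]
  nx <- c(x[-1], x[1]); ny <- c(y[-1], y[1])
  abs(sum(x * ny - nx * y)) / 2
}

#' Sway velocity (SV)
#'
#' Total length of the COP trajectory divided by the recording period.
#'
#' @inheritParams axis_sway
#' @param duration Recording period in seconds; defaults to the trajectory
#'   length over its sampling rate.
#' @return SV in mm/s.
#' @export
sway_velocity <- function(traj, duration = nrow(traj$xy) / traj$fs) {
  stopifnot(inherits(traj, "cop_trajectory"))
  if (duration <= 0) stop_argument("duration must be positive")
  sum(sqrt(rowSums(diff(traj$xy)^2))) / duration
}

#' Sway intensity (SI)
#'
#' RMS of the band-limited (0.1--10.1 Hz) COP acceleration magnitude.
#' Acceleration is obtained per axis by second-order central differences,
#' band-passed with the zero-phase Butterworth cascade, and trimmed by
#' 1 s per end to remove differentiation and filter edge artifacts.
#'
#' @inheritParams axis_sway
#' @param band Acceleration band in Hz, default `c(0.1, 10.1)`.
#' @param trim Seconds trimmed from each end, default 1.
#' @return SI in mm/s^2.
#' @export
sway_intensity <- function(traj, band = c(0.1, 10.1), trim = 1) {
  stopifnot(inherits(traj, "cop_trajectory"))
  fs <- traj$fs
  if (fs <= 2 * band[2]) {
    stop_argument("fs must exceed twice the upper band edge")
  }
  n <- nrow(traj$xy)
  if (n < (2 * trim + 1) * fs + 2) {
    stop_degenerate("trajectory too short for sway-intensity estimation")
  }
  accel <- function(z) (z[3:n] - 2 * z[2:(n - 1)] + z[1:(n - 2)]) * fs^2
  ax <- bandpass_zerophase(accel(traj$xy[, 1]), fs, band)
  ay <- bandpass_zerophase(accel(traj$xy[, 2]), fs, band)
  ntrim <- round(trim * fs)
  ax <- trim_edges(ax, ntrim)
  ay <- trim_edges(ay, ntrim)
  sqrt(mean(ax^2 + ay^2))
}

#' All six sway metrics of a stance recording
#'
#' Trims the run-in from the start and the run-out from the end of the
#' recording, derives the centered COP trajectory of the retained window,
#' and computes TS, SS, MS, SA, SV and SI. With the standard stance
#' protocol (80.5 s, 10 s run-in, 5 s run-out) the analyzed window is
#' 65.5 s.
#'
#' @param rec A [sway_recording()].
#' @param run_in,run_out Leading/trailing seconds excluded from analysis.
#' @param area_mode Passed to [sway_area()].
#' @return Object of class `sway_metrics`: `TS`, `SS`, `MS` (mm), `SA`
#'   (mm^2), `SV` (mm/s), `SI` (mm/s^2), plus `duration` (analyzed s).
#' @export
sway_metrics <- function(rec, run_in = 10, run_out = 5,
                         area_mode = c("hull", "grid")) {
  stopifnot(inherits(rec, "sway_recording"))
  area_mode <- match.arg(area_mode)
  if (run_in < 0 || run_out < 0) stop_argument("run-in/run-out must be >= 0")
  n <- nrow(rec$forces)
  i0 <- round(run_in * rec$fs) + 1L
  i1 <- n - round(run_out * rec$fs)
  if (i1 - i0 + 1L < 2L) {
    stop_argument(sprintf(
      "analyzed window non-positive: %.1f s recording minus %.1f s run-in and %.1f s run-out",
      rec$duration, run_in, run_out))
  }
  win <- sway_recording(rec$forces[i0:i1, , drop = FALSE], rec$fs,
                        rec$sensor_xy)
  traj <- center_of_force(win)
  dur <- nrow(traj$xy) / rec$fs
  axes <- axis_sway(traj)
  structure(
    list(TS = unname(axes["TS"]), SS = unname(axes["SS"]),
         MS = mean_sway(traj),
         SA = sway_area(traj, mode = area_mode),
         SV = sway_velocity(traj, duration = dur),
         SI = sway_intensity(traj),
         duration = dur),
    class = "sway_metrics")
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat(sprintf(
    "TS %.2f SS %.2f MS %.2f mm | SA %.1f mm^2 | SV %.2f mm/s | SI %.2f mm/s^2 (%.1f s)\n",
    x$TS, x$SS, x$MS, x$SA, x$SV, x$SI, x$duration))
  invisible(x)
}
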