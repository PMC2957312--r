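#' Tremor-trace archetype parameters
#'
#' Spectral archetypes for the tremor generator. A trace is a dominant
#' sinusoid (frequency drawn from `f_range`), an optional second harmonic,
#' slow amplitude modulation, and band-limited broadband noise mixed at
#' power fraction `noise_frac`, finally scaled to a requested tremor
#' intensity. The `pd_rest` default is a narrowband 4--6 Hz parkinsonian
#' rest tremor; `control` archetypes are broadband low-amplitude
#' physiological tremor with a weak, widely varying peak.
#'
#' @param name One of `"pd_rest"`, `"pd_postural"`, `"control_rest"`,
#'   `"control_postural"`.
#' @param ... Overrides for individual fields (`f_range`, `harmonic_ratio`,
#'   `am_depth`, `noise_frac`, `fs`, `duration`).
#' @return List of archetype parameters.
#' @export
tremor_archetype <- function(name = c("pd_rest", "pd_postural",
                                      "control_rest", "control_postural"),
                             ...) {
  name <- match.arg(name)
  base <- switch(name,
    pd_rest = list(f_range = c(4.25, 5.75), harmonic_ratio = 0.15,
                   am_depth = 0.3, noise_frac = 0.10),
    pd_postural = list(f_range = c(4.5, 6.5), harmonic_ratio = 0.15,
                       am_depth = 0.3, noise_frac = 0.15),
    control_rest = list(f_range = c(4.5, 12), harmonic_ratio = 0.05,
                        am_depth = 0.3, noise_frac = 0.70),
    control_postural = list(f_range = c(4.5, 12), harmonic_ratio = 0.05,
                            am_depth = 0.3, noise_frac = 0.70))
  p <- utils::modifyList(c(base, list(fs = 125, duration = 8.192,
                                      name = name)),
                         list(...))
  stopifnot(p$noise_frac >= 0, p$noise_frac <= 1,
            p$f_range[1] > 0.9, p$f_range[2] < 15)
  p
}

#' Simulate a tremor acceleration trace
#'
#' Generates a trace from a [tremor_archetype()] and rescales it so that
#' its measured tremor intensity equals `amplitude` (the rescaling is
#' exact because TI is linear in signal scale).
#'
#' @param archetype A [tremor_archetype()] parameter list.
#' @param amplitude Target TI in m/s^2.
#' @param seed Optional integer seed (full determinism per seed).
#' @param label Task tag stored on the trace.
#' @return An [accel_trace()].
#' @examples
#' tr <- simulate_tremor_trace(seed = 7)
#' tremor_metrics(tr)
#' @export
simulate_tremor_trace <- function(archetype = tremor_archetype("pd_rest"),
                                  amplitude = 1.0, seed = NULL,
                                  label = archetype$name) {
  if (!is.null(seed)) set.seed(seed)
  fs <- archetype$fs
  n <- round(fs * archetype$duration)
  t <- (0:(n - 1)) / fs
  f0 <- runif(1, archetype$f_range[1], archetype$f_range[2])
  ph <- runif(3, 0, 2 * pi)
  s <- sin(2 * pi * f0 * t + ph[1]) +
    archetype$harmonic_ratio * sin(2 * pi * 2 * f0 * t + ph[2])
  s <- s * (1 + archetype$am_depth * sin(2 * pi * 0.4 * t + ph[3]))
  nz <- bandpass_zerophase(rnorm(n), fs, c(0.9, 15.0))
  mix <- sqrt(1 - archetype$noise_frac) * s / sqrt(mean(s^2)) +
    sqrt(archetype$noise_frac) * nz / sqrt(mean(nz^2))
  tr <- accel_trace(mix, fs, label = label)
  if (amplitude <= 0) stop_argument("amplitude must be positive")
  scale <- amplitude / tremor_intensity(tr)
  accel_trace(mix * scale, fs, label = label)
}

#' Simulate a tapping series
#'
#' Inter-tap intervals are gamma distributed with mean `1/rate` and
#' coefficient of variation `jitter_cv` (`jitter_cv = 0` gives a perfectly
#' periodic tapper). The process is started well before the recording
#' window (30 mean intervals of burn-in) so the retained window is an
#' approximately stationary renewal process and the expected hit count is
#' `rate * T` without start-up bias.
#'
#' @param rate Mean tap rate, events/s.
#' @param jitter_cv CV of the inter-tap interval.
#' @param T Recording duration, seconds.
#' @param seed Optional integer seed.
#' @param task,side Stored on the returned series.
#' @return A [tap_series()].
#' @export
simulate_taps <- function(rate, jitter_cv = 0.3, T = 10, seed = NULL,
                          task = "finger_tapping", side = "right") {
  if (!is.null(seed)) set.seed(seed)
  if (rate <= 0 || T <= 0) stop_argument("rate and T must be positive")
  burn <- 30 / rate
  if (jitter_cv <= 0) {
    first <- runif(1, 0, 1 / rate)
    hits <- seq(first, T, by = 1 / rate)
  } else {
    k <- 1 / jitter_cv^2
    # draw in blocks until the window is covered
    hits <- numeric(0)
    cur <- -burn
    while (cur <= T) {
      iv <- rgamma(ceiling((T + burn) * rate * 0.5) + 20, shape = k,
                   scale = 1 / (rate * k))
      newt <- cur + cumsum(iv)
      hits <- c(hits, newt)
      cur <- newt[length(newt)]
    }
    hits <- hits[hits >= 0 & hits <= T]
  }
  tap_series(hits, T = T, task = task, side = side)
}

#' Simulate a reaction-time trial set
#'
#' Nine (by default) stimuli are placed in the session window with a
#' minimum inter-stimulus gap of `max_rt` so response windows cannot
#' overlap. Latencies are log-normal with the requested mean and SD
#' (moment matching); a fraction `anticipation_rate` of trials is replaced
#' by anticipatory latencies below 0.10 s (exercising the validity
#' filter), and latencies exceeding `max_rt` are recorded as misses
#' (`NA`).
#'
#' @param mu Target mean latency, s (> 0.10).
#' @param sigma Target latency SD, s.
#' @param anticipation_rate Fraction of trials replaced by anticipatory
#'   responses.
#' @param max_rt Maximum permitted reaction time, s.
#' @param seed Optional integer seed.
#' @param n_stimuli,session_length Stimulus schedule parameters.
#' @return A [reaction_trials()].
#' @export
simulate_reaction_trials <- function(mu = 0.29, sigma = 0.05,
                                     anticipation_rate = 0, max_rt = 2.0,
                                     seed = NULL, n_stimuli = 9,
                                     session_length = 40) {
  if (!is.null(seed)) set.seed(seed)
  if (mu <= 0.10) stop_argument("mu must exceed the 0.10 s validity floor")
  slack <- session_length - n_stimuli * max_rt
  if (slack <= 0) {
    stop_argument("session too short for the stimulus count at this max_rt")
  }
  stim <- sort(runif(n_stimuli, 0, slack)) +
    (0:(n_stimuli - 1)) * max_rt
  rts <- rlnorm_mean_sd(n_stimuli, mu, sigma)
  ant <- runif(n_stimuli) < anticipation_rate
  rts[ant] <- runif(sum(ant), 0.02, 0.09)
  rts[!is.na(rts) & rts > max_rt] <- NA # miss: no click within max_rt
  reaction_trials(stim, rts, max_rt = max_rt,
                  session_length = session_length)
}

#' Sway-path generator parameters
#'
#' The COP path is a mean-centered planar Gaussian process per axis: a
#' slow postural-drift component (white noise low-passed at `f_slow`) plus
#' a faster corrective component (low-passed at `f_fast`) with power
#' fraction `fast_frac`, the sagittal axis scaled by `axis_ratio` relative
#' to the transversal axis. The whole path is rescaled so that the
#' analyzed-window sway velocity equals `sv_target`, which is how the
#' cohort simulator moment-matches sway velocity. The dynamics defaults
#' were calibrated once so the control-group metric ratios (SS/SV, TS/SS,
#' MS/SV) reproduce the reference control cohort.
#'
#' @param group `"control"` or `"pd"`.
#' @param ... Field overrides (`f_slow`, `f_fast`, `fast_frac`,
#'   `axis_ratio`, `sv_target`, `total_force`).
#' @return Parameter list.
#' @export
sway_params <- function(group = c("control", "pd"), ...) {
  group <- match.arg(group)
  base <- switch(group,
    control = list(f_slow = 0.15, f_fast = 1.0, fast_frac = 0.15,
                   axis_ratio = 1.20, sv_target = 7.24),
    pd = list(f_slow = 0.15, f_fast = 1.0, fast_frac = 0.25,
              axis_ratio = 1.98, sv_target = 12.89))
  utils::modifyList(c(base, list(total_force = 70, group = group)),
                    list(...))
}

## low-passed unit-variance Gaussian noise (edge-padded against transients)
lp_noise <- function(n, fs, fc) {
  pad <- min(2000L, 10L * n)
  z <- signal::filtfilt(signal::butter(2, fc / (fs / 2), "low"),
                        rnorm(n + 2L * pad))
  z <- z[(pad + 1L):(pad + n)]
  z / stats::sd(z)
}

## fold coordinates into [-lim, lim] by reflection
reflect_into <- function(z, lim) {
  out <- ((z + lim) %% (4 * lim))
  ifelse(out > 2 * lim, 4 * lim - out, out) - lim
}

#' Simulate a stance (force-plate) recording
#'
#' Generates a COP path per [sway_params()], rescales it to the target
#' sway velocity measured on the analysis window (`run_in`/`run_out`
#' trimmed, as in [sway_metrics()]), and converts it to three vertical
#' force channels by inverting the force-weighted-centroid relation
#' (barycentric coordinates within the sensor triangle) at constant total
#' force. Paths that would leave the sensor triangle are reflected inward
#' with a warning.
#'
#' @param params A [sway_params()] list.
#' @param duration Total recording length, s (including run-in/run-out).
#' @param fs Sampling rate, Hz (default 50).
#' @param seed Optional integer seed.
#' @param run_in,run_out Window trims used when calibrating the path to
#'   `sv_target`; use the same values when analyzing.
#' @param sensor_xy Sensor geometry, default [default_sensor_geometry()].
#' @return A [sway_recording()].
#' @export
simulate_sway <- function(params = sway_params("control"), duration = 80.5,
                          fs = 50, seed = NULL, run_in = 10, run_out = 5,
                          sensor_xy = default_sensor_geometry()) {
  if (!is.null(seed)) set.seed(seed)
  if (duration <= run_in + run_out) {
    stop_argument("duration must cover run-in + run-out + analysis window")
  }
  n <- round(duration * fs)
  mk_axis <- function(scale) {
    scale * (sqrt(1 - params$fast_frac) * lp_noise(n, fs, params$f_slow) +
               sqrt(params$fast_frac) * lp_noise(n, fs, params$f_fast))
  }
  if (params$sv_target <= 0) {
    xy <- matrix(0, n, 2)
  } else {
    xy <- cbind(mk_axis(1), mk_axis(params$axis_ratio))
    i0 <- round(run_in * fs) + 1L
    i1 <- n - round(run_out * fs)
    win <- sweep(xy[i0:i1, , drop = FALSE], 2,
                 colMeans(xy[i0:i1, , drop = FALSE]))
    sv0 <- sum(sqrt(rowSums(diff(win)^2))) / ((i1 - i0 + 1L) / fs)
    xy <- xy * (params$sv_target / sv0)
    xy <- sweep(xy, 2, colMeans(xy))
  }
  # confine to a rectangle inscribed in the sensor triangle
  lim <- c(40, 60)
  if (any(abs(xy[, 1]) > lim[1]) || any(abs(xy[, 2]) > lim[2])) {
    warning("COP path exceeded the sensor triangle; reflected inward")
    xy[, 1] <- reflect_into(xy[, 1], lim[1])
    xy[, 2] <- reflect_into(xy[, 2], lim[2])
  }
  centroid <- colMeans(sensor_xy)
  abs_xy <- sweep(xy, 2, centroid, "+")
  # barycentric weights of each COP point within the sensor triangle
  v1 <- sensor_xy[1, ]; v2 <- sensor_xy[2, ]; v3 <- sensor_xy[3, ]
  det <- (v2[2] - v3[2]) * (v1[1] - v3[1]) +
    (v3[1] - v2[1]) * (v1[2] - v3[2])
  b1 <- ((v2[2] - v3[2]) * (abs_xy[, 1] - v3[1]) +
           (v3[1] - v2[1]) * (abs_xy[, 2] - v3[2])) / det
  b2 <- ((v3[2] - v1[2]) * (abs_xy[, 1] - v3[1]) +
           (v1[1] - v3[1]) * (abs_xy[, 2] - v3[2])) / det
  b3 <- 1 - b1 - b2
  sway_recording(params$total_force * cbind(b1, b2, b3), fs, sensor_xy)
}

# ---------------------------------------------------------------------------
# cohort-level archetypes and simulation

#' Cohort archetype parameters
#'
#' Per-group generator targets for every battery metric: most-affected-side
#' target mean/SD pairs (the reference cohort's group moments), tapping
#' jitter CVs, reaction-trial parameters, sway-path parameters, and the
#' side-asymmetry and spectral-heterogeneity settings. Skewed nonnegative
#' metrics use moment-matched log-normal subject draws; the parkinsonian
#' reaction time is a 0.25 s physiological floor plus a moment-matched
#' log-normal slowing increment (total mean/SD preserved), a family chosen
#' so group moments and nonparametric group separability hold
#' simultaneously.
#'
#' @return Nested list with `pd` and `control` entries.
#' @export
cohort_archetypes <- function() {
  list(
    pd = list(
      rest_TI = c(1.34, 3.02),
      postural_TI = c(1.75, 3.20),
      pronation_supination = list(rate = c(2.45, 0.787), jitter_cv = 0.39),
      finger_tapping = list(rate = c(3.83, 0.989), jitter_cv = 0.33),
      reaction = list(floor = 0.25, inc = c(0.16, 0.207),
                      within_sd = 0.10, anticipation = 0.05),
      sway = sway_params("pd"),
      sway_sv = c(12.89, 7.43),
      # tremulous subjects (probability A/(A + nf_amp_half), increasing in
      # tremor amplitude) get a narrowband 4-6 Hz spectrum; the rest share
      # the control background law, so group F50/SF50 distributions
      # overlap as in the reference cohorts
      f_range = c(4.25, 5.75),
      trem_nf_range = c(0.30, 0.60),
      nf_amp_half = 8.0,
      background = list(f_range = c(2.5, 13), nf_range = c(0.15, 0.90)),
      # lateral asymmetry: better-side value as a fraction of the worse
      # side (inverted for rates); gaps kept wide relative to the
      # within-subject measurement noise so the worse side by latent
      # severity is almost surely the worse side as measured
      asym_TI = c(0.2, 0.7), asym_rate = c(0.75, 0.92),
      asym_RT = c(0.70, 0.90)),
    control = list(
      rest_TI = c(0.10, 0.07),
      postural_TI = c(0.21, 0.30),
      pronation_supination = list(rate = c(3.43, 0.559), jitter_cv = 0.37),
      finger_tapping = list(rate = c(4.63, 0.794), jitter_cv = 0.30),
      reaction = list(floor = 0, inc = c(0.29, 0.058),
                      within_sd = 0.05, anticipation = 0.03),
      sway = sway_params("control"),
      sway_sv = c(7.24, 1.67),
      background = list(f_range = c(2.5, 13), nf_range = c(0.15, 0.90)),
      asym_TI = c(0.5, 1.0), asym_rate = c(0.80, 0.95),
      asym_RT = c(0.75, 0.92)))
}

## quantile-ish binning of a latent amplitude into a 0-4 ordinal item score
## with added ordinal noise
item_from_amplitude <- function(a, cuts, noise_p = 0.25) {
  score <- findInterval(a, cuts)
  flip <- runif(length(a)) < noise_p
  score[flip] <- score[flip] + sample(c(-1L, 1L), sum(flip), replace = TRUE)
  pmin(pmax(score, 0L), 4L)
}

#' Simulate a full subject session
#'
#' Draws one subject's latent severity and per-task parameters from the
#' group archetypes and generates raw recordings for the requested tasks
#' on both sides (stance once). Within-subject task severities share a
#' common latent factor (correlation ~0.7) so tremor amplitude, clinical
#' item scores and bradykinesia co-vary as in patients.
#'
#' @param group `"pd"` or `"control"`.
#' @param subject_id Identifier string.
#' @param archetypes From [cohort_archetypes()].
#' @param tasks Character vector of task names or `"all"`.
#' @param protocol A [default_protocol()]-shaped data frame.
#' @return A [subject_session()].
#' @export
simulate_session <- function(group = c("pd", "control"),
                             subject_id = "S1",
                             archetypes = cohort_archetypes(),
                             tasks = "all",
                             protocol = default_protocol()) {
  group <- match.arg(group)
  a <- archetypes[[group]]
  if (identical(tasks, "all")) tasks <- protocol$task
  z <- rnorm(1) # shared latent severity
  lat <- function() 0.7 * z + sqrt(1 - 0.49) * rnorm(1)
  qdraw <- function(ms, zz = lat()) { # moment-matched lognormal via latent
    p <- lnorm_params(ms[1], ms[2])
    exp(p$meanlog + p$sdlog * zz)
  }
  dominant <- sample(c("right", "left"), 1, prob = c(0.9, 0.1))
  affected <- sample(c("right", "left"), 1)
  other <- setdiff(c("right", "left"), affected)
  rec <- list()
  clinical <- list()
  prow <- function(task) protocol[protocol$task == task, , drop = FALSE]

  tremor_pair <- function(task, ms, arch_label) {
    pr <- prow(task)
    worse <- qdraw(ms)
    better <- worse * runif(1, a$asym_TI[1], a$asym_TI[2])
    amps <- stats::setNames(c(worse, better), c(affected, other))
    for (sd_ in c("right", "left")) {
      amp <- amps[[sd_]]
      tremulous <- group == "pd" &&
        runif(1) < amp / (amp + a$nf_amp_half)
      arch <- if (tremulous) {
        tremor_archetype(arch_label, f_range = a$f_range,
                         noise_frac = runif(1, a$trem_nf_range[1],
                                            a$trem_nf_range[2]),
                         duration = pr$duration)
      } else {
        tremor_archetype(arch_label,
                         f_range = a$background$f_range,
                         noise_frac = runif(1, a$background$nf_range[1],
                                            a$background$nf_range[2]),
                         duration = pr$duration)
      }
      rec[[paste(task, sd_, sep = ".")]] <<-
        simulate_tremor_trace(arch, amplitude = amp, label = task)
    }
    amps
  }
  tap_pair <- function(task, spec) {
    pr <- prow(task)
    worse <- qdraw(spec$rate) # lower rate is worse
    better <- worse / runif(1, a$asym_rate[1], a$asym_rate[2])
    rates <- stats::setNames(c(worse, better), c(affected, other))
    for (sd_ in c("right", "left")) {
      rec[[paste(task, sd_, sep = ".")]] <<-
        simulate_taps(rates[[sd_]], jitter_cv = spec$jitter_cv,
                      T = pr$duration, task = task, side = sd_)
    }
    rates
  }

  if ("rest_tremor" %in% tasks) {
    amps <- tremor_pair("rest_tremor", a$rest_TI,
                        if (group == "pd") "pd_rest" else "control_rest")
    if (group == "pd") {
      clinical$updrs20 <- list(
        right = item_from_amplitude(amps[["right"]],
                                    c(0.2, 0.5, 1.5, 4.0)),
        left = item_from_amplitude(amps[["left"]], c(0.2, 0.5, 1.5, 4.0)))
    }
  }
  if ("postural_tremor" %in% tasks) {
    amps <- tremor_pair("postural_tremor", a$postural_TI,
                        if (group == "pd") "pd_postural"
                        else "control_postural")
    if (group == "pd") {
      clinical$updrs21 <- list(
        right = item_from_amplitude(amps[["right"]],
                                    c(0.25, 0.6, 1.8, 4.5)),
        left = item_from_amplitude(amps[["left"]], c(0.25, 0.6, 1.8, 4.5)))
    }
  }
  if ("pronation_supination" %in% tasks) {
    rates <- tap_pair("pronation_supination", a$pronation_supination)
    if (group == "pd") {
      # item 31 (body bradykinesia): slower alternating movement -> higher
      clinical$updrs31 <- item_from_amplitude(-mean(rates),
                                              c(-3.0, -2.6, -2.2, -1.8))
    }
  }
  if ("finger_tapping" %in% tasks) tap_pair("finger_tapping",
                                            a$finger_tapping)
  if ("reaction" %in% tasks) {
    pr <- prow("reaction")
    r <- a$reaction
    worse <- r$floor + qdraw(r$inc)
    better <- worse * runif(1, a$asym_RT[1], a$asym_RT[2])
    mus <- stats::setNames(c(worse, better), c(affected, other))
    for (sd_ in c("right", "left")) {
      rec[[paste("reaction", sd_, sep = ".")]] <-
        simulate_reaction_trials(mu = mus[[sd_]], sigma = r$within_sd,
                                 anticipation_rate = r$anticipation,
                                 n_stimuli = pr$n_stimuli,
                                 session_length = pr$duration)
    }
  }
  if ("stance" %in% tasks) {
    pr <- prow("stance")
    sv <- qdraw(a$sway_sv)
    rec[["stance"]] <- simulate_sway(
      utils::modifyList(a$sway, list(sv_target = sv)),
      duration = pr$duration, fs = pr$fs,
      run_in = pr$run_in, run_out = pr$run_out)
  }
  if (group == "pd") {
    clinical$hy_stage <- min(max(round(2.3 + 0.7 * z), 1), 4)
  }
  subject_session(subject_id, group, recordings = rec,
                  dominant_side = dominant, clinical = clinical)
}

#' Simulate a cohort of subject sessions
#'
#' Generates `n_pd` parkinsonian and `n_control` control sessions with the
#' group structure of the reference cohorts. Fully deterministic under
#' `seed` (one RNG stream drives subject order, parameters, and signals).
#'
#' @param n_pd,n_control Group sizes (defaults 44 and 28).
#' @param seed Integer seed, recorded on the result.
#' @param tasks Tasks to generate (`"all"` or subset of protocol tasks);
#'   restricting tasks makes metric-specific simulations cheap.
#' @param archetypes From [cohort_archetypes()].
#' @param protocol Battery definition, default [default_protocol()].
#' @param missingness `"none"` (complete sessions, default) or
#'   `"reference"`, which drops per-task recordings to reproduce the
#'   reference study's varying per-metric group sizes (e.g. posturography
#'   in only 7 of 44 patients and 10 of 28 controls).
#' @return List of [subject_session()] objects with attributes `seed`,
#'   `n_pd`, `n_control`.
#' @export
simulate_cohort <- function(n_pd = 44, n_control = 28, seed = 1,
                            tasks = "all",
                            archetypes = cohort_archetypes(),
                            protocol = default_protocol(),
                            missingness = c("none", "reference")) {
  missingness <- match.arg(missingness)
  if (n_pd < 0 || n_control < 0 || n_pd + n_control < 1) {
    stop_argument("need at least one subject")
  }
  set.seed(seed)
  sessions <- c(
    lapply(seq_len(n_pd), function(i) {
      simulate_session("pd", sprintf("PD%02d", i), archetypes, tasks,
                       protocol)
    }),
    lapply(seq_len(n_control), function(i) {
      simulate_session("control", sprintf("CT%02d", i), archetypes, tasks,
                       protocol)
    }))
  if (missingness == "reference") {
    sessions <- apply_reference_missingness(sessions, n_pd, n_control)
  }
  structure(sessions, seed = seed, n_pd = n_pd, n_control = n_control)
}

## reference per-task completeness fractions (per-metric N / group N)
reference_completeness <- function() {
  list(pd = c(rest_tremor = 44, postural_tremor = 44,
              pronation_supination = 40, finger_tapping = 38,
              reaction = 42, stance = 7) / 44,
       control = c(rest_tremor = 28, postural_tremor = 18,
                   pronation_supination = 18, finger_tapping = 18,
                   reaction = 22, stance = 10) / 28)
}

apply_reference_missingness <- function(sessions, n_pd, n_control) {
  frac <- reference_completeness()
  groups <- vapply(sessions, function(s) s$group, character(1))
  for (g in c("pd", "control")) {
    idx <- which(groups == g)
    for (task in names(frac[[g]])) {
      keep_n <- round(frac[[g]][[task]] * length(idx))
      drop_idx <- if (keep_n < length(idx)) {
        sample(idx, length(idx) - keep_n)
      } else integer(0)
      for (i in drop_idx) {
        keys <- grep(paste0("^", task, "(\\.|$)"),
                     names(sessions[[i]]$recordings), value = TRUE)
        sessions[[i]]$recordings[keys] <- NULL
      }
    }
  }
  sessions
}
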