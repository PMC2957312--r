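test_that("generators are fully deterministic under a fixed seed", {
  expect_equal(simulate_tremor_trace(seed = 5),
               simulate_tremor_trace(seed = 5))
  expect_equal(simulate_taps(3, 0.3, seed = 5), simulate_taps(3, 0.3, seed = 5))
  expect_equal(simulate_reaction_trials(seed = 5),
               simulate_reaction_trials(seed = 5))
  expect_equal(simulate_sway(seed = 5)$forces,
               simulate_sway(seed = 5)$forces)
  co1 <- simulate_cohort(2, 2, seed = 7)
  co2 <- simulate_cohort(2, 2, seed = 7)
  expect_equal(co1, co2)
  # byte-identical manifests on disk
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(co1, d1); write_cohort(co2, d2)
  f1 <- readLines(file.path(d1, "PD01", "manifest.json"))
  f2 <- readLines(file.path(d2, "PD01", "manifest.json"))
  expect_identical(f1, f2)
})

test_that("tremor generator hits the requested intensity and archetypal spectrum", {
  for (s in 1:3) {
    tr <- simulate_tremor_trace(amplitude = 0.37, seed = s)
    expect_equal(tremor_intensity(tr), 0.37, tolerance = 0.02)
  }
  noiseless <- simulate_tremor_trace(
    tremor_archetype("pd_rest", noise_frac = 0, am_depth = 0,
                     harmonic_ratio = 0), seed = 2)
  expect_equal(harmonic_index(band_spectrum(noiseless)), 1,
               tolerance = 0.02)
})

test_that("tap generator recovers its rate over replicates and degenerates to periodic", {
  set.seed(55)
  mft <- replicate(200, mean_tap_frequency(simulate_taps(3, 0.3, T = 10)))
  expect_equal(mean(mft), 3, tolerance = 3 * sd(mft) / sqrt(200))
  per <- simulate_taps(4, 0, T = 10, seed = 1)
  expect_equal(tap_frequency_sd(per), 0)
})

test_that("reaction generator schedules 9 stimuli with max_rt gaps and exercises the validity filter", {
  tr <- simulate_reaction_trials(seed = 8)
  expect_length(tr$stimulus_times, 9)
  expect_true(all(diff(tr$stimulus_times) >= tr$max_rt))
  expect_equal(reaction_metrics(tr)$n_valid, 9)
  none <- simulate_reaction_trials(anticipation_rate = 1, seed = 8)
  expect_equal(reaction_metrics(none)$n_valid, 0)
})

test_that("sway generator: zero target freezes the COP, symmetric axes balance TS and SS", {
  still <- simulate_sway(sway_params("control", sv_target = 0), seed = 3)
  m <- sway_metrics(still)
  expect_equal(m$SV, 0)
  expect_equal(m$MS, 0)

  set.seed(66)
  deltas <- replicate(15, {
    rec <- simulate_sway(sway_params("control", axis_ratio = 1))
    m <- sway_metrics(rec)
    m$SS - m$TS
  })
  expect_lt(abs(mean(deltas)), 2 * sd(deltas) / sqrt(15) + 0.2)

  # target sway velocity is reproduced exactly on the analyzed window
  rec <- simulate_sway(sway_params("control", sv_target = 9.9), seed = 4)
  expect_equal(sway_metrics(rec)$SV, 9.9, tolerance = 1e-6)
})

test_that("cohort simulator produces the requested group structure", {
  co <- simulate_cohort(3, 2, seed = 11, tasks = "rest_tremor")
  expect_length(co, 5)
  groups <- vapply(co, function(s) s$group, character(1))
  expect_equal(sum(groups == "pd"), 3)
  expect_equal(sum(groups == "control"), 2)

  # control-only cohorts fail downstream group comparison
  ctl <- simulate_cohort(0, 4, seed = 12, tasks = "rest_tremor")
  tbl <- reduce_most_affected(cohort_metrics(ctl))
  expect_error(compare_cohort(tbl), class = "neurocat_validation")
})

test_that("reference missingness reproduces the per-task group sizes of the source cohorts", {
  co <- simulate_cohort(44, 28, seed = 13, tasks = c("rest_tremor",
                                                     "stance"),
                        missingness = "reference")
  tbl <- cohort_metrics(co)
  expect_equal(sum(!is.na(tbl$stance_SV[tbl$group == "pd"])), 7)
  expect_equal(sum(!is.na(tbl$stance_SV[tbl$group == "control"])), 10)
  expect_equal(sum(!is.na(tbl$rest_tremor_right_TI[tbl$group == "pd"])),
               44)
})

test_that("clinical item scores increase with tremor amplitude within patients", {
  co <- simulate_cohort(44, 0, seed = 14, tasks = "rest_tremor")
  tbl <- cohort_metrics(co)
  cr <- spearman(tbl$rest_tremor_right_TI, tbl$updrs20_right)
  expect_gt(cr$rho, 0.5)
  expect_lt(cr$p, 0.01)
})
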