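test_that("band spectrum is Parseval-consistent and matches a DFT oracle on white noise", {
  set.seed(11)
  for (rep in 1:3) {
    x <- rnorm(4096)
    tr <- accel_trace(x, 125)
    sp <- band_spectrum(tr)
    # Parseval: band power ~ mean square of the band-passed signal
    y <- bandpass_zerophase(x, 125, c(0.9, 15))
    expect_lt(abs(sum(sp$power) - mean(y^2)) / mean(y^2), 0.05)
  }
  # flatness of white noise against the direct DFT periodogram: band-mean
  # power agrees, and no Welch bin dominates
  x <- rnorm(512)
  tr <- accel_trace(x, 125)
  sp <- band_spectrum(tr)
  or <- dft_periodogram_oracle(x, 125)
  keep <- or$freqs >= 0.9 & or$freqs <= 15
  expect_lt(abs(sum(sp$power) - sum(or$power[keep])) /
              sum(or$power[keep]), 0.25)
  expect_lt(max(sp$power), 4 * mean(sp$power))
})

test_that("band spectrum of a sinusoid concentrates at its frequency; zero trace has zero power", {
  sp <- band_spectrum(make_sine_trace(5))
  expect_equal(sp$freqs[which.max(sp$power)], 5, tolerance = sp$df)
  sp0 <- band_spectrum(accel_trace(rep(0, 1024), 125))
  expect_true(all(sp0$power == 0))
  expect_error(band_spectrum(accel_trace(rnorm(100), 125)),
               class = "neurocat_degenerate_input")
  expect_error(band_spectrum(make_sine_trace(5), band = c(70, 80)),
               class = "neurocat_argument")
})

test_that("tremor intensity matches analytic RMS values and scales linearly", {
  expect_equal(tremor_intensity(make_sine_trace(5, A = 1)), 1 / sqrt(2),
               tolerance = 0.01)
  expect_equal(tremor_intensity(accel_trace(rep(0, 1024), 125)), 0)
  t <- (0:2047) / 125
  two <- accel_trace(sin(2 * pi * 5 * t) + 0.5 * sin(2 * pi * 8 * t), 125)
  expect_equal(tremor_intensity(two), sqrt((1 + 0.25) / 2),
               tolerance = 0.01)
  set.seed(21)
  x <- rnorm(1024)
  tr1 <- accel_trace(x, 125)
  tr2 <- accel_trace(2.7 * x, 125)
  expect_equal(tremor_intensity(tr2), 2.7 * tremor_intensity(tr1),
               tolerance = 1e-9)
})

test_that("center frequency: spectral line, flat-noise midpoint, interpolation rule, amplitude invariance", {
  sp <- band_spectrum(make_sine_trace(5))
  expect_equal(center_frequency(sp), 5, tolerance = sp$df)

  set.seed(31)
  f50s <- replicate(12, {
    center_frequency(band_spectrum(accel_trace(rnorm(1024), 125)))
  })
  expect_equal(mean(f50s), (0.9 + 15) / 2, tolerance = 0.45)

  # equal-power lines at 3 and 9 Hz: crossing happens at the end of the
  # 3 Hz bin under in-bin interpolation; cross-check the cumsum oracle
  spec <- structure(list(freqs = c(3, 9), power = c(1, 1),
                         band = c(0.9, 15), df = 0.5),
                    class = "tremor_spectrum")
  expect_equal(center_frequency(spec),
               f50_cumsum_oracle(spec$freqs, spec$power, spec$df))
  expect_equal(center_frequency(spec), 3.25)

  set.seed(32)
  x <- rnorm(1024)
  a <- center_frequency(band_spectrum(accel_trace(x, 125)))
  b <- center_frequency(band_spectrum(accel_trace(5 * x, 125)))
  expect_equal(a, b, tolerance = 1e-9)

  expect_error(center_frequency(band_spectrum(accel_trace(rep(0, 1024),
                                                          125))),
               class = "neurocat_degenerate_input")
})

test_that("frequency dispersion: constant tone ~0, alternating tones match the windowed oracle", {
  expect_lt(frequency_dispersion(make_sine_trace(5)), 0.2)

  fs <- 125
  t <- (0:(8 * fs - 1)) / fs
  blk <- floor(t) %% 2 == 0
  x <- ifelse(blk, sin(2 * pi * 4 * t), sin(2 * pi * 8 * t))
  alt <- accel_trace(x, fs)
  sf50 <- frequency_dispersion(alt)

  # brute-force oracle: per-window F50 from a naive Hann-tapered DFT
  # periodogram and the cumulative-median rule, SD across the same windows
  nwin <- round(2.048 * fs)
  starts <- seq(1, length(x) - nwin + 1, by = nwin / 2)
  wf <- vapply(starts, function(s) {
    or <- dft_periodogram_oracle(x[s:(s + nwin - 1)], fs,
                                 taper = hann_taper(nwin))
    keep <- or$freqs >= 0.9 & or$freqs <= 15
    f50_cumsum_oracle(or$freqs[keep], or$power[keep], fs / nwin)
  }, numeric(1))
  expect_equal(sf50, sd(wf), tolerance = 0.05 * sd(wf))

  expect_gt(sf50, frequency_dispersion(make_sine_trace(5, dur = 8)))
  expect_error(frequency_dispersion(make_sine_trace(5, dur = 2.5)),
               class = "neurocat_degenerate_input")
})

test_that("harmonic index: 1 for a pure tone, low for noise, monotone in spectral concentration", {
  expect_equal(harmonic_index(band_spectrum(make_sine_trace(5))), 1,
               tolerance = 0.02)

  set.seed(41)
  his <- replicate(5, {
    x <- rnorm(1024)
    sp <- band_spectrum(accel_trace(x, 125))
    hi <- harmonic_index(sp)
    expect_equal(hi, lobe_fraction_oracle(sp$power), tolerance = 1e-12)
    hi
  })
  expect_true(all(his < 0.5))

  t <- (0:1023) / 125
  set.seed(42)
  pure <- accel_trace(sin(2 * pi * 5 * t), 125)
  mixed <- accel_trace(sin(2 * pi * 5 * t) + 0.3 * rnorm(1024), 125)
  noise <- accel_trace(rnorm(1024), 125)
  h <- vapply(list(pure, mixed, noise),
              function(tr) harmonic_index(band_spectrum(tr)), numeric(1))
  expect_true(h[1] >= h[2] && h[2] >= h[3])
  expect_true(all(h >= 0 & h <= 1))
})

test_that("bundled tremor metrics recover the parkinsonian rest-tremor archetype", {
  for (s in 1:5) {
    m <- tremor_metrics(simulate_tremor_trace(seed = s))
    expect_gte(m$F50, 4)
    expect_lte(m$F50, 6)
    expect_gt(m$HI, 0.8)
    expect_equal(m$TI, 1.0, tolerance = 0.02)
  }
  expect_error(tremor_metrics(accel_trace(rep(0, 1024), 125)),
               class = "neurocat_degenerate_input")
})
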