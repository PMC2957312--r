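test_that("center of force: symmetric loads, single-sensor loads, and round-trip recovery", {
  sens <- default_sensor_geometry()
  eq <- sway_recording(matrix(20, 100, 3), fs = 50)
  traj <- center_of_force(eq)
  expect_equal(max(abs(traj$xy)), 0, tolerance = 1e-9)
  expect_equal(traj$center, colMeans(sens), tolerance = 1e-9,
               ignore_attr = TRUE)

  one <- sway_recording(cbind(rep(60, 10), rep(0, 10), rep(0, 10)), 50)
  t1 <- center_of_force(one)
  expect_equal(t1$center, sens[1, ], tolerance = 1e-9, ignore_attr = TRUE)

  # round trip: invert the weighted-centroid relation for a known path
  set.seed(13)
  path <- cbind(cumsum(rnorm(200, sd = 0.5)), cumsum(rnorm(200, sd = 0.5)))
  path <- sweep(path, 2, colMeans(path))
  rec <- sway_recording(forces_from_cop(sweep(path, 2, colMeans(sens),
                                              "+")), 50)
  got <- center_of_force(rec)
  expect_equal(got$xy, path, tolerance = 1e-8, ignore_attr = TRUE)

  bad <- sway_recording(rbind(c(1, 1, 1), c(0, 0, 0)), 50)
  expect_error(center_of_force(bad), class = "neurocat_data")
})

test_that("axis sway is the mean absolute per-axis deviation", {
  yline <- cop_trajectory(cbind(rep(0, 50), rnorm(50)), 50)
  expect_equal(unname(axis_sway(yline)["TS"]), 0)
  sq <- cop_trajectory(cbind(rep(c(-3, 3), 50), rep(c(-6.5, 6.5), 50)), 50)
  expect_equal(unname(axis_sway(sq)), c(3, 6.5))
})

test_that("mean sway: degenerate point, circle radius, arithmetic oracle", {
  pt <- cop_trajectory(matrix(0, 10, 2), 50, recenter = FALSE)
  expect_equal(mean_sway(pt), 0)
  th <- seq(0, 2 * pi, length.out = 101)[-101]
  circ <- cop_trajectory(5 * cbind(cos(th), sin(th)), 50)
  expect_equal(mean_sway(circ), 5, tolerance = 1e-9)
  xy <- rbind(c(1, 1), c(-2, 0), c(0.5, -1), c(0.5, 0))
  traj <- cop_trajectory(xy, 50, recenter = FALSE)
  expect_equal(mean_sway(traj), mean(sqrt(rowSums(xy^2))))
})

test_that("sway area: square, interior points ignored, random clouds equal the brute-force hull oracle", {
  sq <- cop_trajectory(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)), 50)
  expect_equal(sway_area(sq), 100)

  tri <- rbind(c(0, 0), c(12, 0), c(0, 9), c(2, 2), c(4, 3), c(1, 1))
  expect_equal(sway_area(cop_trajectory(tri, 50)), 12 * 9 / 2)

  set.seed(17)
  for (n in c(50, 200)) {
    xy <- cbind(rnorm(n, sd = 4), rnorm(n, sd = 2))
    traj <- cop_trajectory(xy, 50)
    expect_equal(sway_area(traj), hull_area_oracle(traj$xy),
                 tolerance = 1e-9)
  }

  flat <- cop_trajectory(cbind(1:5, rep(0, 5)), 50)
  expect_warning(a <- sway_area(flat), "collinear")
  expect_equal(a, 0)
})

test_that("sway velocity is path length over duration", {
  still <- cop_trajectory(matrix(0, 100, 2), 50, recenter = FALSE)
  expect_equal(sway_velocity(still, duration = 2), 0)
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  expect_equal(sway_velocity(cop_trajectory(sq, 50), duration = 10), 4)
})

test_that("sway intensity matches analytic accelerations of circular and sinusoidal motion", {
  fs <- 50
  t <- (0:(30 * fs - 1)) / fs
  r <- 3; f <- 1
  circ <- cop_trajectory(r * cbind(cos(2 * pi * f * t),
                                   sin(2 * pi * f * t)), fs)
  expect_equal(sway_intensity(circ), (2 * pi * f)^2 * r, tolerance = 0.02)

  sine <- cop_trajectory(cbind(2 * sin(2 * pi * 1 * t), rep(0, length(t))),
                         fs)
  expect_equal(sway_intensity(sine), (2 * pi)^2 * 2 / sqrt(2),
               tolerance = 0.02)

  still <- cop_trajectory(matrix(0, 30 * fs, 2), fs, recenter = FALSE)
  expect_equal(sway_intensity(still), 0)
  expect_error(sway_intensity(cop_trajectory(matrix(0, 50, 2), fs)),
               class = "neurocat_degenerate_input")
})

test_that("sway metrics trim run-in/run-out and validate the analyzed window", {
  rec <- simulate_sway(seed = 3)
  m <- sway_metrics(rec)
  expect_equal(m$duration, 65.5, tolerance = 1 / rec$fs)

  short <- sway_recording(matrix(20, 12 * 50, 3), 50)
  expect_error(sway_metrics(short, run_in = 10, run_out = 5),
               class = "neurocat_argument")

  # identity window when no trimming requested
  m0 <- sway_metrics(rec, run_in = 0, run_out = 0)
  expect_equal(m0$duration, rec$duration, tolerance = 1 / rec$fs)
})

test_that("sway metrics scale correctly under rigid translation and spatial scaling", {
  set.seed(19)
  path <- cbind(cumsum(rnorm(1500, sd = 0.3)), cumsum(rnorm(1500, sd = 0.3)))
  path <- sweep(path, 2, colMeans(path))
  path <- path / max(1, max(abs(path)) / 20)
  sens <- default_sensor_geometry()
  mk <- function(p) sway_recording(
    forces_from_cop(sweep(p, 2, colMeans(sens), "+")), 50)
  m1 <- sway_metrics(mk(path), run_in = 0, run_out = 0)
  m2 <- sway_metrics(mk(path + 5), run_in = 0, run_out = 0) # translation
  for (nm in c("TS", "SS", "MS", "SA", "SV", "SI")) {
    expect_equal(m1[[nm]], m2[[nm]], tolerance = 1e-6)
  }
  m3 <- sway_metrics(mk(path * 1.7), run_in = 0, run_out = 0)
  for (nm in c("TS", "SS", "MS", "SV", "SI")) {
    expect_equal(m3[[nm]], 1.7 * m1[[nm]], tolerance = 1e-6)
  }
  expect_equal(m3$SA, 1.7^2 * m1$SA, tolerance = 1e-6)
})
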