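test_that("most affected side follows the metric direction and breaks ties to the dominant side", {
  expect_equal(most_affected_side(1.2, 0.4, "TI")$side, "right")
  expect_equal(most_affected_side(4.5, 3.1, "MFT")$side, "left")
  expect_equal(most_affected_side(0.3, 0.5, "RT")$side, "left")
  tie <- most_affected_side(2, 2, "TI", dominant = "left")
  expect_equal(tie$side, "left")
  expect_true(tie$flagged)
  onesided <- most_affected_side(NA, 1.1, "TI")
  expect_equal(onesided$side, "left")
  expect_true(onesided$flagged)
  expect_error(higher_is_worse("XYZ"), class = "neurocat_argument")
})

test_that("Mann-Whitney: separation, symmetry, and exact p equals exhaustive enumeration", {
  sep <- mann_whitney(1:3, 4:6)
  expect_equal(sep$U, 0)

  same <- mann_whitney(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(same$U, 4 * 4 / 2, tolerance = 1)
  expect_gt(same$p, 0.5)

  set.seed(71)
  for (i in 1:5) {
    a <- round(rnorm(5), 6); b <- round(rnorm(5, 0.8), 6)
    got <- mann_whitney(a, b)
    expect_equal(got$p, mw_exact_oracle(a, b), tolerance = 1e-12)
    # complementary orientation: U_A + U_B = n1 n2 on tie-free data
    expect_equal(got$U + mann_whitney(b, a)$U, 25)
  }
  expect_error(mann_whitney(1, 1:5), class = "neurocat_validation")
})

test_that("Mann-Whitney is invariant under strictly monotone transforms and the approximation tracks exact p", {
  set.seed(72)
  a <- rlnorm(8); b <- rlnorm(8, 0.5)
  expect_equal(mann_whitney(a, b)$p, mann_whitney(log(a), log(b))$p)
  expect_equal(mann_whitney(a, b)$U, mann_whitney(a^3, b^3)$U)

  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    pe <- mann_whitney(a, b)$p # exact path (n = 10, tie-free)
    pa <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE)$p.value)
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("Spearman: monotone extremes, tie handling against the rank oracle, invariance", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman(x, x^2 + 1)$rho, 1)
  expect_equal(spearman(x, -sqrt(x))$rho, -1)

  xt <- c(1, 2, 2, 3, 3, 4)
  yt <- c(2, 1, 3, 3, 5, 4)
  expect_equal(spearman(xt, yt)$rho, spearman_oracle(xt, yt))

  set.seed(73)
  a <- rnorm(20); b <- a + rnorm(20)
  expect_equal(spearman(a, b)$rho, spearman(exp(a), b^3)$rho)

  const <- spearman(rep(1, 5), 1:5)
  expect_true(const$flagged && is.na(const$rho))
  expect_error(spearman(1:2, 2:1), class = "neurocat_validation")
})

test_that("cohort comparison reports one row per metric with pairwise-complete Ns", {
  set.seed(74)
  tbl <- data.frame(group = rep(c("pd", "control"), c(12, 10)),
                    m1 = c(rnorm(12, 2), rnorm(10, 0)),
                    m2 = rnorm(22))
  tbl$m2[c(1, 15)] <- NA
  cmp <- compare_cohort(tbl, metrics = c("m1", "m2"))
  expect_equal(nrow(cmp), 2)
  expect_equal(cmp$n_pd[cmp$metric == "m2"], 11)
  expect_equal(cmp$n_control[cmp$metric == "m2"], 9)
  expect_true(cmp$significant[cmp$metric == "m1"])

  none <- compare_cohort(tbl, alpha = 1e-12, metrics = "m2")
  expect_false(any(none$significant))

  single <- compare_cohort(tbl, metrics = "m1")
  expect_equal(nrow(single), 1)
})

test_that("the most-affected-side reduction picks each task's side by its primary metric", {
  set.seed(75)
  co <- simulate_cohort(2, 2, seed = 42, tasks = c("rest_tremor",
                                                   "reaction"))
  tbl <- cohort_metrics(co)
  red <- reduce_most_affected(tbl)
  expect_equal(red$rest_tremor_TI,
               pmax(tbl$rest_tremor_right_TI, tbl$rest_tremor_left_TI))
  expect_equal(red$reaction_RT,
               pmax(tbl$reaction_right_RT, tbl$reaction_left_RT))
  # secondary metric follows the side chosen by the primary
  worse_right <- tbl$rest_tremor_right_TI > tbl$rest_tremor_left_TI
  expect_equal(red$rest_tremor_F50,
               ifelse(worse_right, tbl$rest_tremor_right_F50,
                      tbl$rest_tremor_left_F50))
})
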