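#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm rlnorm rgamma runif sd fft var complete.cases
#' @importFrom utils read.csv write.csv
NULL

stop_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("neurocat_degenerate_input", "error")))
}

stop_argument <- function(msg) {
  stop(errorCondition(msg, class = c("neurocat_argument", "error")))
}

stop_data <- function(msg) {
  stop(errorCondition(msg, class = c("neurocat_data", "error")))
}

stop_validation <- function(msg) {
  stop(errorCondition(msg, class = c("neurocat_validation", "error")))
}

#' Moment-matched log-normal parameters
#'
#' Solves for `meanlog`/`sdlog` so the log-normal distribution has the
#' requested arithmetic mean and standard deviation. Used throughout the
#' cohort simulator for skewed nonnegative metrics.
#'
#' @param mean,sd Target arithmetic mean (> 0) and standard deviation (>= 0).
#' @return List with `meanlog` and `sdlog`.
#' @export
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Draw moment-matched log-normal variates
#'
#' @param n Number of draws.
#' @inheritParams lnorm_params
#' @return Numeric vector of length `n`.
#' @export
rlnorm_mean_sd <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  p <- lnorm_params(mean, sd)
  rlnorm(n, p$meanlog, p$sdlog)
}

## sample SD (n-1 denominator) is the single SD convention of the package;
## stats::sd already does this, alias kept for readability at call sites
sample_sd <- function(x) stats::sd(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
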