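# Fixture builders and independent brute-force oracles used across tests.

make_sine_trace <- function(f, A = 1, fs = 125, dur = 8.192, phase = 0,
                            label = "rest") {
  t <- (0:(round(fs * dur) - 1)) / fs
  accel_trace(A * sin(2 * pi * f * t + phase), fs, label = label)
}

# periodogram computed sample-by-sample from the DFT definition (O(n^2)),
# one-sided, scaled so the sum equals the mean square of x; optional
# taper applied before the transform
dft_periodogram_oracle <- function(x, fs, taper = NULL) {
  if (!is.null(taper)) x <- x * taper / sqrt(mean(taper^2))
  n <- length(x)
  nf <- n %/% 2 + 1
  p <- numeric(nf)
  for (k in 0:(nf - 1)) {
    ex <- exp(-2i * pi * k * (0:(n - 1)) / n)
    p[k + 1] <- Mod(sum(x * ex))^2 / n^2
  }
  p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  list(freqs = (0:(nf - 1)) * fs / n, power = p)
}

hann_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# cumulative-spectrum median with in-bin interpolation, written as a plain
# scan independent of the package implementation
f50_cumsum_oracle <- function(freqs, power, df) {
  tot <- sum(power)
  acc <- 0
  for (i in seq_along(power)) {
    if (acc + power[i] >= tot / 2) {
      return(freqs[i] - df / 2 + (tot / 2 - acc) / power[i] * df)
    }
    acc <- acc + power[i]
  }
  stop("no crossing")
}

# dominant-lobe power fraction by exhaustive scan over all bins
lobe_fraction_oracle <- function(p) {
  imax <- which.max(p)
  in_lobe <- rep(FALSE, length(p))
  in_lobe[imax] <- TRUE
  for (i in rev(seq_len(imax - 1))) {        # walk left
    if (p[i] <= p[i + 1]) in_lobe[i] <- TRUE else break
  }
  if (imax < length(p)) {
    for (i in (imax + 1):length(p)) {        # walk right
      if (p[i] <= p[i - 1]) in_lobe[i] <- TRUE else break
    }
  }
  sum(p[in_lobe]) / sum(p)
}

# convex-hull area by brute force: a segment (i, j) is a hull edge iff all
# remaining points lie on one side; vertices ordered by angle, shoelace
hull_area_oracle <- function(xy) {
  n <- nrow(xy)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- xy[j, ] - xy[i, ]
    cr <- (xy[, 1] - xy[i, 1]) * d[2] - (xy[, 2] - xy[i, 2]) * d[1]
    if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
      on_hull[i] <- TRUE
      on_hull[j] <- TRUE
    }
  }
  v <- xy[on_hull, , drop = FALSE]
  ctr <- colMeans(v)
  v <- v[order(atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all
# choose(n1+n2, n1) group labelings
mw_exact_oracle <- function(a, b) {
  pool <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(pool)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(pool), n1)
  us <- apply(combs, 2, u_of)
  pl <- mean(us <= obs)
  pu <- mean(us >= obs)
  min(1, 2 * min(pl, pu))
}

# average-rank Spearman computed by hand
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# forces realizing a known COP path on the default sensor triangle
forces_from_cop <- function(xy, total = 70,
                            sensors = default_sensor_geometry()) {
  v1 <- sensors[1, ]; v2 <- sensors[2, ]; v3 <- sensors[3, ]
  det <- (v2[2] - v3[2]) * (v1[1] - v3[1]) +
    (v3[1] - v2[1]) * (v1[2] - v3[2])
  b1 <- ((v2[2] - v3[2]) * (xy[, 1] - v3[1]) +
           (v3[1] - v2[1]) * (xy[, 2] - v3[2])) / det
  b2 <- ((v3[2] - v1[2]) * (xy[, 1] - v3[1]) +
           (v1[1] - v3[1]) * (xy[, 2] - v3[2])) / det
  total * cbind(b1, b2, 1 - b1 - b2)
}
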