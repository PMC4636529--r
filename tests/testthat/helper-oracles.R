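# Independent oracles. These deliberately avoid the package's own code
# paths: quadrature instead of the normal CDF, bisection instead of the
# quantile function, explicit loops instead of vectorised formulas.

# Composite Simpson quadrature of (1/sqrt(2*pi)) * integral_{-l}^{+l} exp(-t^2/2) dt.
simpson_gauss_mass <- function(lambda, panels = 1e6) {
  if (lambda == 0) {
    return(0)
  }
  h <- 2 * lambda / panels
  t <- seq(-lambda, lambda, length.out = panels + 1)
  f <- exp(-t^2 / 2)
  w <- rep(c(4, 2), length.out = panels - 1)
  (h / 3) * (f[1] + f[panels + 1] + sum(w * f[2:panels])) / sqrt(2 * pi)
}

# Bisection over the quadrature oracle.
bisect_lambda <- function(p, tol = 1e-10, panels = 2e5) {
  lo <- 0
  hi <- 40
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (simpson_gauss_mass(mid, panels) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Literal transcription of the printed threshold-multiplier formula.
k_literal <- function(lambda_a, lambda_b, n) {
  (2 * (n - 1)) / (2 * (n - 1) - lambda_b^2) *
    (lambda_a + lambda_b * sqrt((n * lambda_a^2 + 2 * (n - 1) - lambda_b^2) /
      (2 * n * (n - 1))))
}

# Loop-based time-domain HRV definitions.
naive_sdnn <- function(rr) {
  m <- 0
  for (v in rr) m <- m + v
  m <- m / length(rr)
  ss <- 0
  for (v in rr) ss <- ss + (v - m)^2
  sqrt(ss / (length(rr) - 1))
}

naive_rmssd <- function(rr) {
  ss <- 0
  for (i in 2:length(rr)) ss <- ss + (rr[i] - rr[i - 1])^2
  sqrt(ss / (length(rr) - 1))
}

naive_pnn50 <- function(rr) {
  cnt <- 0
  for (i in 2:length(rr)) if (abs(rr[i] - rr[i - 1]) > 50) cnt <- cnt + 1
  100 * cnt / (length(rr) - 1)
}

constant_series <- function(n, value = 100, unit = "bpm") {
  beat_series(rep(value, n), unit = unit)
}
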