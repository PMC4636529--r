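#' Two-sided standard-normal mass within a symmetric band
#'
#' `gauss_error_probability(lambda)` is the probability that a standard
#' normal variate falls in `[-lambda, +lambda]`, i.e. the Gauss error
#' function evaluated at `lambda / sqrt(2)`:
#' \deqn{\mathrm{Erf}(\lambda/\sqrt2) = \frac{1}{\sqrt{2\pi}}
#'   \int_{-\lambda}^{+\lambda} e^{-t^2/2}\,dt .}
#' Computed through the exact normal CDF as `2 * pnorm(lambda) - 1`; it is
#' strictly increasing in `lambda`, 0 at 0, and approaches 1 as
#' `lambda` grows (1 to machine precision by `lambda = 40`).
#'
#' @param lambda Non-negative threshold, in standard deviations. Vectorised.
#' @return Probability in `[0, 1)`.
#' @seealso [solve_lambda()] for the inverse.
#' @examples
#' gauss_error_probability(2) # ~ 0.9545
#' @export
gauss_error_probability <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be non-negative and finite.",
      class = "avechr_domain_error"
    )
  }
  2 * pnorm(lambda) - 1
}

#' Solve for the band half-width attaining a confidence level
#'
#' Inverts [gauss_error_probability()]: returns the unique `lambda` such
#' that a standard normal variate falls in `[-lambda, +lambda]` with
#' probability `p`. Computed through the exact normal quantile function,
#' `qnorm((1 + p) / 2)`.
#'
#' @param p Confidence level, strictly between 0 and 1. Vectorised.
#' @return The band half-width `lambda > 0`.
#' @examples
#' solve_lambda(0.75) # ~ 1.1503
#' @export
solve_lambda <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    abort("`p` must lie strictly between 0 and 1.",
      class = "avechr_domain_error"
    )
  }
  qnorm((1 + p) / 2)
}

#' Graf–Henning threshold multiplier k
#'
#' The outlier criterion compares a candidate's deviation from its window
#' mean against `k` times the window standard deviation, where
#' \deqn{k = \frac{2(n-1)}{2(n-1)-\lambda_b^2}\left[\lambda_a +
#'   \lambda_b\sqrt{\frac{n\lambda_a^2 + 2(n-1) - \lambda_b^2}
#'   {2n(n-1)}}\right]}
#' with `n` the number of values the window statistics are computed from.
#' The correction terms inflate the plain band half-width `lambda_a` to
#' account for the mean and standard deviation being estimated from the
#' window rather than known: with `lambda_b = 0` the formula collapses to
#' `lambda_a` exactly, and `k` decreases towards `lambda_a` as `n` grows.
#'
#' @param lambda_a,lambda_b Band half-widths derived from the confidence
#'   level (see [detection_config()] for how they are resolved).
#' @param n Number of values entering the window statistics; must satisfy
#'   `n >= 3` and `lambda_b^2 < 2 * (n - 1)`.
#' @return The threshold multiplier `k > 0`.
#' @examples
#' compute_k(solve_lambda(0.75), solve_lambda(0.75), 40) # ~ 1.409
#' @export
compute_k <- function(lambda_a, lambda_b, n) {
  if (any(n < 3)) {
    abort("`n` must be at least 3.", class = "avechr_domain_error")
  }
  if (any(!is.finite(lambda_a)) || any(!is.finite(lambda_b)) ||
    any(lambda_a < 0) || any(lambda_b < 0)) {
    abort("`lambda_a` and `lambda_b` must be non-negative and finite.",
      class = "avechr_domain_error"
    )
  }
  if (any(lambda_b^2 >= 2 * (n - 1))) {
    abort(
      "Constraint violated: lambda_b^2 must be < 2*(n - 1), otherwise the leading factor of k is undefined or negative.",
      class = "avechr_domain_error"
    )
  }
  two_nm1 <- 2 * (n - 1)
  two_nm1 / (two_nm1 - lambda_b^2) *
    (lambda_a + lambda_b * sqrt((n * lambda_a^2 + two_nm1 - lambda_b^2) /
      (2 * n * (n - 1))))
}

#' Detection configuration
#'
#' Bundles the tunable parameters of the windowed outlier criterion.
#'
#' @param p_level Confidence level `P` in (0, 1), default 0.75; see Details
#'   for how it trades missed artifacts against deleted genuine beats.
#' @param half_window Beats taken on each side of a candidate (default 20,
#'   i.e. a 41-value string including the candidate, roughly a 30-s span
#'   at canine heart rates).
#' @param min_half_window Smallest acceptable one-sided context near the
#'   series boundaries (default 10). Beats with less context on either side
#'   are reported as untested rather than silently passed.
#' @param lambda_mode `"equal"` (default) sets
#'   `lambda_a = lambda_b = solve_lambda(p_level)`; `"explicit"` takes both
#'   from `lambda_a`/`lambda_b`, for users wiring in the original tabulated
#'   solutions from the Graf–Henning source.
#' @param lambda_a,lambda_b Used only when `lambda_mode = "explicit"`.
#' @param n_convention `"exclude_candidate"` (default): `n` in the `k`
#'   formula is the number of values actually entering the window mean and
#'   SD, the candidate being excluded (40 for a full window);
#'   `"include_candidate"` adds one.
#' @param unit Unit detection operates in; defaults to `"bpm"`, the unit in
#'   which transmission artifacts present as sharp spikes.
#'
#' @details A lower `p_level` narrows the band `[-lambda, +lambda]` and so
#'   shrinks `k`: the criterion flags more readily, raising the probability
#'   of deleting a value that is not actually an artifact. A higher
#'   `p_level` widens the band, raising the probability of keeping a true
#'   artifact. The default 0.75 deliberately prefers the former risk, on
#'   the grounds that a missed artifact typically distorts time-domain
#'   variability more than the loss of one genuine beat.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(p_level = 0.75, half_window = 20L,
                             min_half_window = 10L,
                             lambda_mode = c("equal", "explicit"),
                             lambda_a = NULL, lambda_b = NULL,
                             n_convention = c(
                               "exclude_candidate",
                               "include_candidate"
                             ),
                             unit = c("bpm", "ms")) {
  lambda_mode <- match.arg(lambda_mode)
  n_convention <- match.arg(n_convention)
  unit <- match.arg(unit)
  if (!is.finite(p_level) || p_level <= 0 || p_level >= 1) {
    abort("`p_level` must lie strictly between 0 and 1.",
      class = "avechr_domain_error"
    )
  }
  half_window <- as.integer(half_window)
  min_half_window <- as.integer(min_half_window)
  if (min_half_window < 2L || half_window < min_half_window) {
    abort("Need half_window >= min_half_window >= 2.",
      class = "avechr_domain_error"
    )
  }
  if (lambda_mode == "equal") {
    lambda_a <- lambda_b <- solve_lambda(p_level)
  } else {
    if (is.null(lambda_a) || is.null(lambda_b) ||
      !is.finite(lambda_a) || !is.finite(lambda_b) ||
      lambda_a <= 0 || lambda_b <= 0) {
      abort("Explicit mode needs positive finite lambda_a and lambda_b.",
        class = "avechr_domain_error"
      )
    }
  }
  structure(
    list(
      p_level = p_level, half_window = half_window,
      min_half_window = min_half_window, lambda_mode = lambda_mode,
      lambda_a = lambda_a, lambda_b = lambda_b,
      n_convention = n_convention, unit = unit
    ),
    class = "detection_config"
  )
}

#' @export
print.detection_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Detection config: P = %g, window = +/-%d beats (min %d/side), ",
      "lambda_mode = %s (lambda_a = %.6f, lambda_b = %.6f), n = %s, unit = %s\n"
    ),
    x$p_level, x$half_window, x$min_half_window, x$lambda_mode,
    x$lambda_a, x$lambda_b, x$n_convention, x$unit
  ))
  invisible(x)
}

k_for_window <- function(config, n_used) {
  n <- if (config$n_convention == "include_candidate") n_used + 1L else n_used
  compute_k(config$lambda_a, config$lambda_b, n)
}

# Scalar decision core shared by test_candidate and scan_series.
gh_decide <- function(window_values, candidate_value, config) {
  n_used <- length(window_values)
  m <- sum(window_values) / n_used
  s <- sqrt(sum((window_values - m)^2) / (n_used - 1))
  k <- k_for_window(config, n_used)
  # Literal criterion: |x_g - xbar| > k |s|. With s = 0 any nonzero
  # deviation flags; an exactly equal value does not.
  list(
    window_mean = m, window_sd = s, n_used = n_used, k = k,
    is_outlier = abs(candidate_value - m) > k * abs(s)
  )
}

#' Test one candidate value against its surrounding window
#'
#' Applies the Graf–Henning criterion `|x_g - xbar| > k |s|`, where the mean
#' `xbar` and standard deviation `s` (sample, `n - 1` denominator) are
#' computed over the window values only — the candidate is excluded — and
#' `k` comes from [compute_k()] under the configured conventions. With a
#' zero-variance window, any nonzero deviation flags and an exactly equal
#' value does not.
#'
#' @param window_values Values surrounding the candidate (candidate
#'   excluded); at least `2 * min_half_window` of them.
#' @param candidate_value The value under test, `x_g`.
#' @param config A [detection_config()].
#' @param index Optional 0-based beat index recorded in the verdict.
#' @return A one-row tibble (the outlier verdict) with columns `index`,
#'   `candidate_value`, `window_mean`, `window_sd`, `n_used`, `k`,
#'   `is_outlier`, `method`.
#' @examples
#' test_candidate(rep(100, 40), 160, detection_config())$is_outlier # TRUE
#' @export
test_candidate <- function(window_values, candidate_value,
                           config = detection_config(), index = NA_integer_) {
  if (!inherits(config, "detection_config")) {
    abort("`config` must be a detection_config.", class = "avechr_error")
  }
  if (length(window_values) < 2L * config$min_half_window) {
    abort(sprintf(
      "Window too short: %d values, need at least %d.",
      length(window_values), 2L * config$min_half_window
    ), class = "avechr_context_error")
  }
  d <- gh_decide(window_values, candidate_value, config)
  tibble(
    index = as.integer(index), candidate_value = candidate_value,
    window_mean = d$window_mean, window_sd = d$window_sd,
    n_used = d$n_used, k = d$k, is_outlier = d$is_outlier,
    method = "algorithm"
  )
}
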