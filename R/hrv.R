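#' Time-domain HRV and heart-rate descriptive statistics
#'
#' Computes the standard time-domain summaries from the beat series exactly
#' as passed — no detrending, interpolation, or other preprocessing:
#'
#' * `sdnn` — sample standard deviation (n - 1 denominator) of the RR
#'   intervals, in ms;
#' * `rmssd` — root mean square of successive RR differences, in ms;
#' * `pnn50` — percentage of successive RR differences whose absolute value
#'   *strictly exceeds* 50 ms, out of the `n - 1` successive pairs;
#' * `hr_mean`, `hr_median`, `hr_sd` — mean, median and sample SD of the
#'   instantaneous heart rate in bpm.
#'
#' HRV is always computed on the ms representation and the HR statistics on
#' the bpm representation, whatever unit the series is stored in.
#'
#' @param series A [beat_series] of at least 2 beats.
#' @return A one-row tibble: `hr_mean`, `hr_median`, `hr_sd` (bpm), `sdnn`,
#'   `rmssd` (ms), `pnn50` (percent), `n_beats`.
#' @examples
#' hrv_summary(beat_series(rep(800, 10), unit = "ms"))
#' @export
hrv_summary <- function(series) {
  assert_beat_series(series)
  if (nrow(series) < 2L) {
    abort("HRV needs at least 2 beats (no successive pairs otherwise).",
      class = "avechr_error"
    )
  }
  rr <- series_values(as_ms(series))
  hr <- series_values(as_bpm(series))
  d <- diff(rr)
  tibble(
    hr_mean = mean(hr),
    hr_median = median(hr),
    hr_sd = sd(hr),
    sdnn = sd(rr),
    rmssd = sqrt(mean(d^2)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    n_beats = length(rr)
  )
}

#' Percent change between two HRV summaries
#'
#' Reports `100 * (after - before) / before` for every parameter. A zero
#' baseline cannot support a percent change: when `before == 0` the change
#' is the undefined-change sentinel `NA`, unless `after` equals it too, in
#' which case the change is 0 (nothing moved).
#'
#' @param before,after One-row summaries from [hrv_summary()] for the same
#'   subject/segment.
#' @return A tibble with one row per parameter: `parameter`, `before`,
#'   `after`, `pct_change`.
#' @export
compare_hrv <- function(before, after) {
  params <- c("hr_mean", "hr_median", "hr_sd", "sdnn", "rmssd", "pnn50")
  b <- as.double(before[1, params])
  a <- as.double(after[1, params])
  pct <- ifelse(b == 0, ifelse(a == b, 0, NA_real_), 100 * (a - b) / b)
  tibble(parameter = params, before = b, after = a, pct_change = pct)
}
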