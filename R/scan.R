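#' Scan a whole series for outliers in a single pass
#'
#' Every beat with sufficient context is tested against the values
#' surrounding it (up to `half_window` on each side, candidate excluded from
#' the mean and SD) using the Graf–Henning criterion. All verdicts are
#' computed from the *original* series in one pass — the single-step
#' procedure: the candidate set is fixed up front rather than grown by
#' iterative delete-and-rescan. Beats closer than `min_half_window` to either
#' end are reported as untested; beats between `min_half_window` and
#' `half_window` from an end are tested against a truncated window.
#'
#' Detection runs in the configured unit (default bpm); the series is
#' converted if needed.
#'
#' @param series A [beat_series].
#' @param config A [detection_config()].
#' @return An object of class `avec_scan`: a list with `verdicts` (a tibble
#'   with one row per beat: `index`, `candidate_value`, `window_mean`,
#'   `window_sd`, `n_used`, `k`, `is_outlier`, `tested`, `method`),
#'   `flagged_indices` (0-based, ascending), `error_fraction` (flagged
#'   count / series length), `n_beats`, plus the `series` (in detection
#'   unit) and `config` used.
#' @seealso [tidy.avec_scan()], [glance.avec_scan()], [exclusion_check()],
#'   [resolve_overlaps()]
#' @export
scan_series <- function(series, config = detection_config()) {
  assert_beat_series(series)
  if (!inherits(config, "detection_config")) {
    abort("`config` must be a detection_config.", class = "avechr_error")
  }
  n <- nrow(series)
  min_n <- 2L * config$min_half_window + 1L
  if (n < min_n) {
    abort(sprintf(
      "Series has %d beats; scanning needs at least %d (2 * min_half_window + 1).",
      n, min_n
    ), class = "avechr_error")
  }
  det <- convert_unit(series, config$unit)
  x <- series_values(det)
  hw <- config$half_window
  mhw <- config$min_half_window

  mean_v <- sd_v <- k_v <- rep(NA_real_, n)
  n_used <- rep(NA_integer_, n)
  flag <- rep(NA, n)
  tested <- rep(FALSE, n)

  for (i in seq_len(n)) {
    left <- min(hw, i - 1L)
    right <- min(hw, n - i)
    if (left < mhw || right < mhw) next
    w <- x[c(seq.int(i - left, i - 1L), seq.int(i + 1L, i + right))]
    d <- gh_decide(w, x[i], config)
    mean_v[i] <- d$window_mean
    sd_v[i] <- d$window_sd
    k_v[i] <- d$k
    n_used[i] <- d$n_used
    flag[i] <- d$is_outlier
    tested[i] <- TRUE
  }

  verdicts <- tibble(
    index = det[["beat"]], candidate_value = x,
    window_mean = mean_v, window_sd = sd_v, n_used = n_used, k = k_v,
    is_outlier = flag, tested = tested, method = "algorithm"
  )
  flagged <- verdicts$index[which(tested & flag)]
  structure(
    list(
      verdicts = verdicts,
      flagged_indices = flagged,
      error_fraction = length(flagged) / n,
      n_beats = n,
      series = det,
      config = config
    ),
    class = "avec_scan"
  )
}

#' @export
print.avec_scan <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "AVEC scan: %d beats, %d tested, %d flagged (%.2f%% errors)%s\n",
    g$n_beats, g$n_tested, g$n_flagged, 100 * g$error_fraction,
    if (g$excluded) " -- EXCLUDED (> 5% errors)" else ""
  ))
  invisible(x)
}

#' Tidy a scan into its per-beat verdicts
#'
#' @param x An `avec_scan`.
#' @param ... Unused.
#' @return The verdict tibble, one row per beat.
#' @method tidy avec_scan
#' @export
tidy.avec_scan <- function(x, ...) x$verdicts

#' One-row summary of a scan
#'
#' @param x An `avec_scan`.
#' @param threshold Exclusion threshold on the error fraction (default 0.05).
#' @param ... Unused.
#' @return A one-row tibble: `n_beats`, `n_tested`, `n_flagged`,
#'   `error_fraction`, `excluded`.
#' @method glance avec_scan
#' @export
glance.avec_scan <- function(x, threshold = 0.05, ...) {
  tibble(
    n_beats = x$n_beats,
    n_tested = sum(x$verdicts$tested),
    n_flagged = length(x$flagged_indices),
    error_fraction = x$error_fraction,
    excluded = x$error_fraction > threshold
  )
}

#' Apply the 5 % exclusion rule
#'
#' A recording is excluded from further analysis when *more than* the
#' threshold fraction of its beats are flagged as errors (strict inequality:
#' exactly 5 % of 100 beats is retained).
#'
#' @param scan An `avec_scan` from [scan_series()].
#' @param threshold Error-fraction threshold, default 0.05.
#' @return A one-row tibble: `error_fraction`, `threshold`, `excluded`.
#' @export
exclusion_check <- function(scan, threshold = 0.05) {
  if (!inherits(scan, "avec_scan")) {
    abort("`scan` must be an avec_scan.", class = "avechr_error")
  }
  tibble(
    error_fraction = scan$error_fraction,
    threshold = threshold,
    excluded = scan$error_fraction > threshold
  )
}
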