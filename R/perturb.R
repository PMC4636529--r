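#' Deletion-versus-replacement perturbation experiment
#'
#' Quantifies how sensitive the HR and HRV summaries are to the two
#' correction strategies, on a series presumed free of artifacts: for each
#' fraction, a set of beat positions is drawn uniformly at random and either
#' deleted or replaced by the mean of the 5 preceding and 5 subsequent
#' surviving values; every summary statistic is then compared with its
#' unperturbed value. The same drawn positions are used for both strategies
#' at a given fraction, so the contrast isolates the strategy.
#'
#' Random positions avoid the first and last 5 beats so that mean
#' replacement is always well defined. Perturbation operates on the ms
#' representation (HRV's native unit); HR statistics come from the bpm
#' conversion of the perturbed series.
#'
#' @param series A [beat_series] with no flagged outliers.
#' @param fractions Fractions of beats to perturb, each in (0, 0.1].
#' @param strategies Subset of `c("delete", "replace_mean")`.
#' @param seed Integer seed making the position draws reproducible.
#' @return A long tibble: `fraction`, `strategy`, `parameter`, `before`,
#'   `after`, `pct_change`.
#' @export
perturbation_experiment <- function(series,
                                    fractions = c(0.01, 0.02, 0.03, 0.04, 0.05),
                                    strategies = c("delete", "replace_mean"),
                                    seed = NULL) {
  assert_beat_series(series)
  strategies <- match.arg(strategies, several.ok = TRUE)
  if (any(fractions <= 0) || any(fractions > 0.1)) {
    abort("`fractions` must lie in (0, 0.1].", class = "avechr_domain_error")
  }
  ms <- as_ms(series)
  n <- nrow(ms)
  if (n < 12L) {
    abort("Series too short for a perturbation experiment.",
      class = "avechr_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  before <- hrv_summary(ms)
  eligible <- ms[["beat"]][seq.int(6L, n - 5L)] # avoid first/last 5 beats

  out <- list()
  for (f in fractions) {
    n_pick <- round(f * n)
    if (n_pick < 1L) {
      warn(sprintf("Fraction %g selects no beat for n = %d; skipped.", f, n))
      next
    }
    picked <- sort(sample(eligible, n_pick))
    plan <- tibble(index = picked, method = "manual")
    for (strat in strategies) {
      pert <- apply_corrections(ms, plan, strat)$series
      cmp <- compare_hrv(before, hrv_summary(pert))
      cmp$fraction <- f
      cmp$strategy <- strat
      out[[length(out) + 1L]] <- cmp
    }
  }
  if (length(out) == 0L) {
    return(tibble(
      fraction = double(), strategy = character(), parameter = character(),
      before = double(), after = double(), pct_change = double()
    ))
  }
  dplyr::bind_rows(out)[, c(
    "fraction", "strategy", "parameter",
    "before", "after", "pct_change"
  )]
}

#' Reshape a perturbation result into the report layout
#'
#' One row per parameter, one column per fraction-strategy combination
#' (e.g. `delete_1%`, `replace_mean_5%`), holding percent changes.
#'
#' @param result A tibble from [perturbation_experiment()].
#' @return A wide tibble.
#' @export
perturbation_report <- function(result) {
  wide <- result
  wide$column <- sprintf("%s_%g%%", wide$strategy, 100 * wide$fraction)
  tidyr::pivot_wider(
    wide[, c("parameter", "column", "pct_change")],
    names_from = "column", values_from = "pct_change"
  )
}
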