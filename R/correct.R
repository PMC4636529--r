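#' Order flagged candidates and re-test within overlapping windows
#'
#' Turns the flagged set of a scan into an ordered correction plan. The
#' candidate set is fixed by the single-pass scan; this step only decides
#' *order* and weeds out candidates that stop looking like outliers once a
#' more extreme neighbour is removed:
#'
#' * Candidates whose windows do not overlap are independent; they enter the
#'   plan in series order.
#' * Within a group of overlapping windows, the most extreme candidate
#'   (largest `|x_g - xbar| / s`, computed from the current context) is
#'   planned first. The remaining candidates in the group are then re-tested
#'   against the re-formed window — the surviving values on both sides joined
#'   across the gap, exactly as the split series is recombined after a
#'   deletion — and dropped if they no longer satisfy the criterion.
#'
#' Note that a moderate artifact right next to an extreme one is often
#' *masked* at scan time (the extreme value inflates its window SD) and so
#' never becomes a candidate; such companions are the province of the visual
#' pass, not of this re-ordering.
#'
#' @param scan An `avec_scan` from [scan_series()].
#' @param config A [detection_config()]; defaults to the one used by the
#'   scan.
#' @return The correction plan: a tibble with one row per planned beat, in
#'   application order, with columns `step`, `index` (0-based), `value`,
#'   `window_mean`, `window_sd`, `n_used`, `k`, `deviation`
#'   (`|x - xbar| / max(s, eps)` against the context it was planned under)
#'   and `method`.
#' @export
resolve_overlaps <- function(scan, config = NULL) {
  if (!inherits(scan, "avec_scan")) {
    abort("`scan` must be an avec_scan.", class = "avechr_error")
  }
  config <- config %||% scan$config
  x <- series_values(scan$series)
  ids <- scan$series[["beat"]]
  eps <- 1e-12
  flagged <- scan$flagged_indices
  empty_plan <- tibble(
    step = integer(), index = integer(), value = double(),
    window_mean = double(), window_sd = double(), n_used = integer(),
    k = double(), deviation = double(), method = character()
  )
  if (length(flagged) == 0L) {
    return(empty_plan)
  }

  pos_of <- match(flagged, ids) # 1-based positions in the series
  # Windows of candidates i, j overlap iff |i - j| <= 2 * half_window.
  gap <- diff(pos_of)
  cluster <- cumsum(c(1L, as.integer(gap > 2L * config$half_window)))

  removed <- logical(length(x))
  retest <- function(p) {
    # Re-form the window around position p from surviving values only.
    left <- integer(0)
    q <- p - 1L
    while (q >= 1L && length(left) < config$half_window) {
      if (!removed[q]) left <- c(q, left)
      q <- q - 1L
    }
    right <- integer(0)
    q <- p + 1L
    while (q <= length(x) && length(right) < config$half_window) {
      if (!removed[q]) right <- c(right, q)
      q <- q + 1L
    }
    if (length(left) < config$min_half_window ||
      length(right) < config$min_half_window) {
      return(NULL) # insufficient surviving context; keep original verdict
    }
    gh_decide(x[c(left, right)], x[p], config)
  }

  rows <- list()
  step <- 0L
  for (cl in unique(cluster)) {
    pending <- pos_of[cluster == cl]
    while (length(pending) > 0L) {
      stats <- lapply(pending, retest)
      # Candidates with insufficient surviving context keep their scan-time
      # verdict and stats.
      for (j in seq_along(stats)) {
        if (is.null(stats[[j]])) {
          v <- scan$verdicts[match(ids[pending[j]], scan$verdicts$index), ]
          stats[[j]] <- list(
            window_mean = v$window_mean, window_sd = v$window_sd,
            n_used = v$n_used, k = v$k, is_outlier = TRUE
          )
        }
      }
      still <- vapply(stats, function(s) isTRUE(s$is_outlier), logical(1))
      pending <- pending[still]
      stats <- stats[still]
      if (length(pending) == 0L) break
      dev <- vapply(seq_along(pending), function(j) {
        abs(x[pending[j]] - stats[[j]]$window_mean) /
          max(stats[[j]]$window_sd, eps)
      }, double(1))
      top <- which.max(dev)
      p <- pending[top]
      st <- stats[[top]]
      step <- step + 1L
      rows[[step]] <- tibble(
        step = step, index = ids[p], value = x[p],
        window_mean = st$window_mean, window_sd = st$window_sd,
        n_used = as.integer(st$n_used), k = st$k, deviation = dev[top],
        method = "algorithm"
      )
      removed[p] <- TRUE
      pending <- pending[-top]
    }
  }
  if (length(rows) == 0L) empty_plan else dplyr::bind_rows(rows)
}

#' Apply a correction plan to a series
#'
#' Two strategies are available, and neither can ever insert a value or
#' reorder the survivors:
#'
#' * `delete`: planned beats are removed; the output length is the input
#'   length minus the plan size and the surviving values are an exact
#'   subsequence of the input.
#' * `replace_mean`: each planned beat is replaced by the arithmetic mean of
#'   the 5 preceding and 5 subsequent *surviving* values (i.e. skipping
#'   other planned beats); the length is unchanged. Near a boundary the
#'   available neighbours are used, with a minimum of 3 per side.
#'
#' @param series A [beat_series].
#' @param plan A plan from [resolve_overlaps()], or any tibble with an
#'   `index` column of 0-based beat indices (a `method` column is honoured).
#' @param strategy `"delete"` or `"replace_mean"`.
#' @return A list with `series` (the corrected [beat_series]) and `log`
#'   (a [correction_log] that replays to exactly the corrected series).
#' @examples
#' s <- beat_series(rep(600, 100), unit = "ms")
#' apply_corrections(s, tibble::tibble(index = 10L), "delete")$series
#' @export
apply_corrections <- function(series, plan,
                              strategy = c("delete", "replace_mean")) {
  assert_beat_series(series)
  strategy <- match.arg(strategy)
  if (!is.data.frame(plan) || !"index" %in% names(plan)) {
    abort("`plan` must be a data frame with an `index` column.",
      class = "avechr_error"
    )
  }
  n <- nrow(series)
  vals <- series_values(series)
  pos <- match(as.integer(plan$index), series[["beat"]])
  if (anyNA(pos)) {
    abort("Plan contains indices not present in the series.",
      class = "avechr_error"
    )
  }
  method <- if ("method" %in% names(plan)) {
    as.character(plan$method)
  } else {
    rep("algorithm", nrow(plan))
  }

  if (nrow(plan) == 0L) {
    log <- correction_log(NULL, source_length = n)
    return(list(series = series, log = log))
  }

  if (strategy == "delete") {
    edits <- tibble(
      index = pos - 1L, original_value = vals[pos],
      action = "delete", replacement_value = NA_real_, method = method
    )
  } else {
    planned <- logical(n)
    planned[pos] <- TRUE
    surv <- which(!planned)
    repl <- vapply(pos, function(p) {
      pre <- surv[surv < p]
      post <- surv[surv > p]
      if (length(pre) < 3L || length(post) < 3L) {
        abort(sprintf(
          "replace_mean needs at least 3 surviving values on each side of beat %d.",
          series[["beat"]][p]
        ), class = "avechr_context_error")
      }
      nb <- c(utils::tail(pre, 5L), utils::head(post, 5L))
      mean(vals[nb])
    }, double(1))
    edits <- tibble(
      index = pos - 1L, original_value = vals[pos],
      action = "replace", replacement_value = repl, method = method
    )
  }
  log <- correction_log(edits, source_length = n)
  list(series = replay_log(series, log), log = log)
}

#' Full correction workflow: visual edits, scan, resolve, apply
#'
#' Runs the complete procedure on one recording: optional visual deletions
#' first (the human decisions), then the single-pass algorithmic scan, the
#' 5 % exclusion check, most-extreme-first resolution of overlapping
#' candidates, and the chosen correction strategy. The combined log is
#' expressed against the *original* series, so a single replay reproduces
#' the final corrected series.
#'
#' @param series A [beat_series].
#' @param config A [detection_config()].
#' @param strategy `"delete"` or `"replace_mean"`.
#' @param manual_edits Optional tibble of visual deletions (column `index`,
#'   0-based in the original series), e.g. from [read_manual_edits()].
#' @param threshold Exclusion threshold (default 0.05).
#' @return A list: `series` (corrected), `log` (combined [correction_log]
#'   against the original series), `scan`, `plan`, `exclusion` (from
#'   [exclusion_check()]).
#' @export
correct_series <- function(series, config = detection_config(),
                           strategy = c("delete", "replace_mean"),
                           manual_edits = NULL, threshold = 0.05) {
  assert_beat_series(series)
  strategy <- match.arg(strategy)
  n0 <- nrow(series)
  working <- series
  visual_edits <- NULL
  if (!is.null(manual_edits) && nrow(manual_edits) > 0L) {
    me <- apply_manual_edits(series, manual_edits)
    working <- me$series
    visual_edits <- as_tibble(me$log)
  }
  scan <- scan_series(working, config)
  excl <- exclusion_check(scan, threshold)
  plan <- resolve_overlaps(scan, config)
  res <- apply_corrections(working, plan, strategy)

  # Map algorithmic edits (positions in the working series) back to original
  # beat ids; visual deletions already carry original ids.
  alg <- as_tibble(res$log)
  if (nrow(alg) > 0L) alg$index <- working[["beat"]][alg$index + 1L]
  combined <- correction_log(
    dplyr::bind_rows(visual_edits, alg),
    source_length = n0, excluded = excl$excluded
  )
  list(
    series = res$series, log = combined, scan = scan, plan = plan,
    exclusion = excl
  )
}
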