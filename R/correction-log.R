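#' Construct a correction log
#'
#' A correction log is an ordered, replayable record of the edits that turn an
#' original beat series into its corrected version. Each edit names the
#' 0-based index *in the original series*, the original value, the action
#' (`delete` or `replace`), the replacement value (for `replace` only) and the
#' method that decided it (`algorithm`, `visual`, or `manual`). By
#' construction a log can never insert a value, so the corrected series is
#' always at most as long as the original and surviving values keep their
#' original relative order — corrections never introduce a time shift.
#'
#' @param edits A data frame with columns `index`, `original_value`, `action`,
#'   `replacement_value`, `method` (zero rows allowed).
#' @param source_length Length of the original series the log applies to.
#' @param excluded Logical; whether the recording was excluded from analysis
#'   (more than 5 % errors).
#' @return A tibble of class `correction_log` with attributes
#'   `source_length` and `excluded`.
#' @export
correction_log <- function(edits = NULL, source_length, excluded = FALSE) {
  if (is.null(edits) || nrow(edits) == 0L) {
    edits <- tibble(
      index = integer(), original_value = double(),
      action = character(), replacement_value = double(), method = character()
    )
  }
  edits <- as_tibble(edits)[, c(
    "index", "original_value", "action",
    "replacement_value", "method"
  )]
  edits$index <- as.integer(edits$index)
  edits$original_value <- as.double(edits$original_value)
  edits$replacement_value <- as.double(edits$replacement_value)
  source_length <- as.integer(source_length)

  if (anyDuplicated(edits$index)) {
    abort("Correction-log indices must be unique.", class = "avechr_error")
  }
  if (nrow(edits) > 0L &&
    (min(edits$index) < 0L || max(edits$index) >= source_length)) {
    abort(sprintf(
      "Correction-log indices must lie in [0, %d).", source_length
    ), class = "avechr_error")
  }
  if (!all(edits$action %in% c("delete", "replace"))) {
    abort("`action` must be 'delete' or 'replace'.", class = "avechr_error")
  }
  if (!all(edits$method %in% c("algorithm", "visual", "manual"))) {
    abort("`method` must be 'algorithm', 'visual' or 'manual'.",
      class = "avechr_error"
    )
  }
  if (any(edits$action == "replace" & !is.finite(edits$replacement_value))) {
    abort("Replace edits need a finite replacement_value.",
      class = "avechr_error"
    )
  }
  if (any(edits$action == "delete" & !is.na(edits$replacement_value))) {
    abort("Delete edits must not carry a replacement_value.",
      class = "avechr_error"
    )
  }
  edits <- edits[order(edits$index), ]
  new_tibble(edits,
    source_length = source_length, excluded = isTRUE(excluded),
    class = "correction_log"
  )
}

#' @export
print.correction_log <- function(x, ...) {
  cat(sprintf(
    "# A correction log: %d edit(s) on %d beats%s\n",
    nrow(x), attr(x, "source_length"),
    if (attr(x, "excluded")) " [EXCLUDED: > 5% errors]" else ""
  ))
  NextMethod()
}

#' Replay a correction log on its source series
#'
#' Applies replacements, then removes deleted beats, reproducing the corrected
#' series exactly. Surviving beats keep their original 0-based index in the
#' `beat` column, so deletions show up as gaps in the coordinate, never as a
#' shift.
#'
#' @param series The original [beat_series] the log was recorded against.
#' @param log A [correction_log].
#' @return The corrected [beat_series].
#' @export
replay_log <- function(series, log) {
  assert_beat_series(series)
  if (!inherits(log, "correction_log")) {
    abort("`log` must be a correction_log.", class = "avechr_error")
  }
  if (attr(log, "source_length") != nrow(series)) {
    abort(sprintf(
      "Log was recorded against %d beats but the series has %d: not replayable.",
      attr(log, "source_length"), nrow(series)
    ), class = "avechr_consistency_error")
  }
  vals <- series_values(series)
  pos <- log$index + 1L
  if (nrow(log) > 0L &&
    any(abs(vals[pos] - log$original_value) > 1e-9 * pmax(1, abs(log$original_value)))) {
    abort("Log original values do not match the series: not replayable.",
      class = "avechr_consistency_error"
    )
  }
  repl <- log$action == "replace"
  vals[pos[repl]] <- log$replacement_value[repl]
  keep <- setdiff(seq_along(vals), pos[log$action == "delete"])
  beat_series(vals[keep],
    unit = series_unit(series), label = series_label(series),
    device_range = attr(series, "device_range", exact = TRUE),
    beat = series[["beat"]][keep]
  )
}
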