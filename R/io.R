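#' Read a beat series from a CSV file
#'
#' @param path Path to a CSV file with a header row.
#' @param unit Unit the file's values are in (`"bpm"` or `"ms"`).
#' @param col Column holding the beats: a name or a 1-based position.
#'   Defaults to a column named `value` if present, otherwise the first
#'   column that is not the `beat` index column.
#' @param label Optional label for the series; defaults to the file name.
#' @return A [beat_series].
#' @export
read_beat_csv <- function(path, unit = c("bpm", "ms"), col = NULL,
                          label = NULL) {
  unit <- match.arg(unit)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "avechr_io_error")
  }
  # columns come in as text and are converted with R's own (correctly
  # rounded) parser, so read(write(x)) is bit-exact
  df <- suppressWarnings(
    readr::read_csv(path,
      col_types = readr::cols(.default = readr::col_character()),
      show_col_types = FALSE, progress = FALSE
    )
  )
  if (nrow(df) == 0L) {
    abort(sprintf("No data rows in %s.", path), class = "avechr_parse_error")
  }
  if (is.null(col)) {
    col <- if ("value" %in% names(df)) {
      "value"
    } else {
      setdiff(names(df), "beat")[1]
    }
  } else if (is.numeric(col)) {
    col <- names(df)[[as.integer(col)]]
  }
  if (!col %in% names(df)) {
    abort(sprintf("Column '%s' not found in %s.", col, path),
      class = "avechr_parse_error"
    )
  }
  raw <- df[[col]]
  vals <- suppressWarnings(as.double(raw))
  bad <- which(is.na(vals) | !is.finite(vals) | vals <= 0)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-numeric or non-positive value at data row %d of %s: '%s'.",
      bad[1], path, as.character(raw[bad[1]])
    ), class = "avechr_parse_error")
  }
  beat_series(vals, unit = unit, label = label %||% basename(path))
}

#' Write a beat series to CSV
#'
#' Writes columns `beat` (0-based index) and `value` with a header row, at
#' full double precision so that write-then-read round-trips exactly.
#'
#' @param series A [beat_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beat_csv <- function(series, path) {
  assert_beat_series(series)
  df <- as_tibble(series)[, c("beat", "value")]
  # 17 significant digits round-trip any double exactly
  df$value <- sprintf("%.17g", df$value)
  readr::write_csv(df, path, progress = FALSE, quote = "none")
  invisible(path)
}

#' Read a Polar HRM text export
#'
#' Reads the `[HRData]` section of an HRM file recorded in RR mode: one
#' integer RR interval (ms) per line. All other sections are tolerated and
#' ignored. Multi-column `[HRData]` rows (recordings with speed/cadence/
#' altitude channels) are rejected: only the RR-only recording mode is
#' supported.
#'
#' @param path Path to an HRM file.
#' @param label Optional label; defaults to the file name.
#' @return A [beat_series] in ms.
#' @export
read_hrm <- function(path, label = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "avechr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  start <- which(trimws(lines) == "[HRData]")
  if (length(start) == 0L) {
    abort(sprintf("No [HRData] section in %s: not an HRM file?", path),
      class = "avechr_format_error"
    )
  }
  body <- lines[seq.int(start[1] + 1L, length.out = length(lines) - start[1])]
  next_section <- grep("^\\[", trimws(body))
  if (length(next_section) > 0L) body <- body[seq_len(next_section[1] - 1L)]
  body <- trimws(body)
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    abort(sprintf("[HRData] section of %s is empty.", path),
      class = "avechr_format_error"
    )
  }
  multi <- grep("[\t ]", body)
  if (length(multi) > 0L) {
    abort(sprintf(
      "Multi-column [HRData] row %d in %s: only RR-only recordings (one RR ms per line) are supported.",
      multi[1], path
    ), class = "avechr_format_error")
  }
  bad <- grep("^[0-9]+$", body, invert = TRUE)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Non-integer RR value at [HRData] line %d of %s: '%s'.",
      bad[1], path, body[bad[1]]
    ), class = "avechr_parse_error")
  }
  beat_series(as.double(body),
    unit = "ms", label = label %||% basename(path),
    device_range = polar_device_range
  )
}

#' Write a beat series as a minimal HRM file
#'
#' Serialises the series as an RR-mode HRM text file: a small `[Params]`
#' header followed by `[HRData]` with one integer RR (ms) per line. The HRM
#' format stores whole milliseconds, so values are rounded; series in bpm are
#' converted first.
#'
#' @param series A [beat_series].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hrm <- function(series, path) {
  assert_beat_series(series)
  rr <- round(series_values(as_ms(series)))
  writeLines(
    c(
      "[Params]", "Version=106", "SMode=00000000", "Interval=238",
      "", "[HRData]", format(rr, scientific = FALSE, trim = TRUE)
    ),
    path
  )
  invisible(path)
}

#' Read and write correction logs
#'
#' The on-disk form is a CSV with columns `index`, `original_value`,
#' `action`, `replacement_value`, `method`, preceded by two comment lines
#' carrying the log metadata (`# source_length:` and `# excluded:`).
#' Serialisation is lossless: `read_correction_log(write_correction_log(x))`
#' reproduces `x`.
#'
#' @param log A [correction_log].
#' @param path File path.
#' @return `write_correction_log()` returns `path` invisibly;
#'   `read_correction_log()` returns a [correction_log].
#' @export
write_correction_log <- function(log, path) {
  if (!inherits(log, "correction_log")) {
    abort("`log` must be a correction_log.", class = "avechr_error")
  }
  header <- c(
    sprintf("# source_length: %d", attr(log, "source_length")),
    sprintf("# excluded: %s", attr(log, "excluded"))
  )
  df <- as_tibble(log)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  df$original_value <- fmt(df$original_value)
  df$replacement_value <- fmt(df$replacement_value)
  body <- utils::capture.output(
    readr::write_csv(df, stdout(), na = "", progress = FALSE, quote = "none")
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_correction_log
#' @export
read_correction_log <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "avechr_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  src <- sub(".*source_length:\\s*", "", grep("source_length", meta, value = TRUE)[1])
  exc <- sub(".*excluded:\\s*", "", grep("excluded", meta, value = TRUE)[1])
  if (is.na(src)) {
    abort(sprintf("Missing '# source_length:' header in %s.", path),
      class = "avechr_format_error"
    )
  }
  edits <- readr::read_csv(path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(.default = readr::col_character())
  )
  edits$index <- as.integer(edits$index)
  edits$original_value <- as.double(edits$original_value)
  edits$replacement_value <- as.double(edits$replacement_value)
  correction_log(edits,
    source_length = as.integer(src),
    excluded = identical(toupper(trimws(exc)), "TRUE")
  )
}

#' Read a manual-edit file
#'
#' Visual-inspection decisions enter the pipeline as a CSV of `index`
#' (0-based beat index in the original series) and free-text `reason`. They
#' are applied as deletions with method `visual` *before* the algorithmic
#' scan, mirroring the workflow in which clearly discontinuous values are
#' removed by eye first and the algorithm handles the unclear cases.
#'
#' @param path Path to a CSV with columns `index` and (optionally) `reason`.
#' @return A tibble with columns `index` and `reason`.
#' @export
read_manual_edits <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "avechr_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"index" %in% names(df)) {
    abort(sprintf("Manual-edit file %s needs an 'index' column.", path),
      class = "avechr_format_error"
    )
  }
  tibble(
    index = as.integer(df$index),
    reason = if ("reason" %in% names(df)) as.character(df$reason) else NA_character_
  )
}

#' Apply visual deletions before the algorithmic scan
#'
#' @param series A [beat_series].
#' @param edits A tibble with an `index` column (0-based indices to delete),
#'   as returned by [read_manual_edits()].
#' @return A list with `series` (the edited [beat_series]) and `log`
#'   (a [correction_log] of method-`visual` deletions).
#' @export
apply_manual_edits <- function(series, edits) {
  assert_beat_series(series)
  idx <- sort(unique(as.integer(edits$index)))
  log <- correction_log(
    tibble(
      index = idx,
      original_value = series_values(series)[idx + 1L],
      action = "delete",
      replacement_value = NA_real_,
      method = "visual"
    ),
    source_length = nrow(series)
  )
  list(series = replay_log(series, log), log = log)
}
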