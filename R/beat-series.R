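#' Polar RS800CX recordable range, in beats per minute
#'
#' The chest-belt monitor records instantaneous heart rate between 15 and
#' 240 bpm; values outside this range cannot originate from the device.
#'
#' @export
polar_device_range <- c(15, 240)

#' Construct a beat series
#'
#' A beat series is an ordered sequence of beat-to-beat measurements, either
#' instantaneous heart rate in beats per minute (`"bpm"`) or interbeat (RR)
#' intervals in milliseconds (`"ms"`). The beat index — not wall-clock time —
#' is the canonical coordinate; indices are 0-based in all files and logs
#' (figure labels are 1-based, a display concern handled by the plot
#' functions). Elapsed time, when needed, is the running sum of RR intervals.
#'
#' @param values Numeric vector of strictly positive, finite measurements in
#'   recording order.
#' @param unit `"bpm"` or `"ms"`.
#' @param label Optional free-text subject/session identifier.
#' @param device_range Optional `c(min, max)` recordable range in bpm
#'   (e.g. [polar_device_range]). When supplied, values whose bpm conversion
#'   falls outside the range raise a warning.
#' @param beat Optional integer vector of original 0-based beat indices; used
#'   internally when a series is derived from another by deletion so that
#'   surviving beats keep their original coordinates.
#'
#' @return A tibble of class `beat_series` with columns `beat` (0-based
#'   index) and `value`, and attributes `unit`, `label`, `device_range`.
#' @examples
#' beat_series(c(600, 650, 600), unit = "ms")
#' @export
beat_series <- function(values, unit = c("bpm", "ms"), label = NULL,
                        device_range = NULL, beat = NULL) {
  unit <- match.arg(unit)
  values <- as.double(values)
  if (length(values) == 0L) {
    abort("`values` must contain at least one beat.", class = "avechr_error")
  }
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad) > 0L) {
    abort(
      sprintf(
        "All beat values must be strictly positive and finite; offending beat index (0-based): %d (value %s).",
        bad[1] - 1L, format(values[bad[1]])
      ),
      class = "avechr_error"
    )
  }
  if (is.null(beat)) {
    beat <- seq_along(values) - 1L
  } else {
    beat <- as.integer(beat)
    stopifnot(length(beat) == length(values), !is.unsorted(beat))
  }
  if (!is.null(device_range)) {
    stopifnot(length(device_range) == 2L, device_range[1] < device_range[2])
    bpm <- if (unit == "bpm") values else 60000 / values
    n_out <- sum(bpm < device_range[1] | bpm > device_range[2])
    if (n_out > 0L) {
      warn(sprintf(
        "%d value(s) fall outside the device range [%g, %g] bpm.",
        n_out, device_range[1], device_range[2]
      ))
    }
  }
  new_tibble(
    list(beat = beat, value = values),
    unit = unit,
    label = label %||% NA_character_,
    device_range = device_range,
    class = "beat_series"
  )
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf(
    "# A beat series: %d beats [%s]%s\n",
    nrow(x), series_unit(x),
    if (is.na(series_label(x))) "" else paste0(" - ", series_label(x))
  ))
  NextMethod()
}

#' Accessors for beat-series metadata
#'
#' @param x A [beat_series].
#' @return `series_unit()` returns `"bpm"` or `"ms"`; `series_label()` the
#'   label; `series_values()` the bare numeric vector.
#' @export
series_unit <- function(x) attr(x, "unit", exact = TRUE)

#' @rdname series_unit
#' @export
series_label <- function(x) attr(x, "label", exact = TRUE)

#' @rdname series_unit
#' @export
series_values <- function(x) x[["value"]]

assert_beat_series <- function(x, arg = "series") {
  if (!inherits(x, "beat_series")) {
    abort(sprintf("`%s` must be a beat_series (see `beat_series()`).", arg),
      class = "avechr_error"
    )
  }
  invisible(x)
}

#' Convert a beat series between bpm and ms
#'
#' Instantaneous heart rate and interbeat interval are reciprocal:
#' `hr_bpm = 60000 / rr_ms`. The conversion is an involution up to floating
#' point; converting to the current unit is a no-op.
#'
#' @param series A [beat_series].
#' @param to Target unit, `"bpm"` or `"ms"`.
#' @return A [beat_series] in the target unit.
#' @examples
#' convert_unit(beat_series(600, unit = "ms"), "bpm") # 100 bpm
#' @export
convert_unit <- function(series, to = c("bpm", "ms")) {
  assert_beat_series(series)
  to <- match.arg(to)
  if (identical(series_unit(series), to)) {
    return(series)
  }
  beat_series(60000 / series_values(series),
    unit = to,
    label = series_label(series),
    device_range = attr(series, "device_range", exact = TRUE),
    beat = series[["beat"]]
  )
}

#' @rdname convert_unit
#' @export
as_ms <- function(series) convert_unit(series, "ms")

#' @rdname convert_unit
#' @export
as_bpm <- function(series) convert_unit(series, "bpm")

#' Elapsed time at each beat
#'
#' The cumulative sum of RR intervals, in seconds, ending at each beat.
#' Used e.g. to slice the first 30 s of a recording.
#'
#' @param series A [beat_series].
#' @return Numeric vector of elapsed seconds, one per beat.
#' @export
elapsed_time <- function(series) {
  cumsum(series_values(as_ms(series))) / 1000
}
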