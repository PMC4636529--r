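#' Block plots for visual inspection
#'
#' Splits the recording into consecutive blocks (default 200 beats, a
#' comfortable width for judging discontinuity by eye) and draws each block
#' as its own panel of value against beat number. Flagged beats, when a scan
#' is supplied, are marked and annotated with their beat number and value.
#'
#' Axis labels are 1-based beat numbers — the convention used when reading
#' plots aloud — while all files and logs remain 0-based.
#'
#' @param series A [beat_series].
#' @param scan Optional `avec_scan` of the same series; its flagged beats
#'   are annotated.
#' @param block_size Beats per panel, at least 50 (default 200).
#' @param annotate_flags Draw index/value labels at flagged beats?
#' @return A ggplot object faceted by block
#'   (`ceiling(n / block_size)` panels).
#' @export
plot_blocks <- function(series, scan = NULL, block_size = 200L,
                        annotate_flags = TRUE) {
  assert_beat_series(series)
  block_size <- as.integer(block_size)
  if (block_size < 50L) {
    abort("`block_size` must be at least 50.", class = "avechr_error")
  }
  df <- as_tibble(series)
  df$beat_1based <- df$beat + 1L
  df$block <- (seq_len(nrow(df)) - 1L) %/% block_size + 1L
  df$block_label <- sprintf("beats %d-%d", (df$block - 1L) * block_size + 1L,
    df$block * block_size)
  df$block_label <- factor(df$block_label, levels = unique(df$block_label))

  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beat_1based, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~block_label, ncol = 1L, scales = "free_x") +
    ggplot2::labs(
      x = "beat number",
      y = sprintf("heart rate [%s]", series_unit(series)),
      title = series_label(series)
    ) +
    ggplot2::theme_minimal()

  if (!is.null(scan) && length(scan$flagged_indices) > 0L) {
    fl <- df[df$beat %in% scan$flagged_indices, , drop = FALSE]
    p <- p + ggplot2::geom_point(data = fl, colour = "red", size = 1.6)
    if (annotate_flags) {
      fl$flag_label <- sprintf("%d: %.0f", fl$beat_1based, fl$value)
      p <- p + ggplot2::geom_text(
        data = fl, ggplot2::aes(label = .data$flag_label),
        vjust = -0.6, size = 2.6, colour = "red"
      )
    }
  }
  p
}

#' Before/after overlay against the original beat index
#'
#' Draws the original series and its corrected version on the *same* beat
#' axis: deleted beats are simply absent from the after-trace, leaving
#' visible gaps, never a shift — the after-trace can only ever cover a
#' subset of the original beat positions.
#'
#' @param before The original [beat_series].
#' @param log The [correction_log] recorded against it; the after-trace is
#'   obtained by [replay_log()] (a log that does not replay cleanly raises a
#'   consistency error).
#' @param before_color,after_color Trace colours (defaults red and blue).
#' @return A ggplot object with one layer per trace.
#' @export
plot_overlay <- function(before, log, before_color = "red",
                         after_color = "blue") {
  assert_beat_series(before)
  after <- replay_log(before, log)
  df_b <- as_tibble(before)[, c("beat", "value")]
  df_b$trace <- "before"
  df_a <- as_tibble(after)[, c("beat", "value")]
  df_a$trace <- "after"
  df <- dplyr::bind_rows(df_b, df_a)
  df$beat_1based <- df$beat + 1L
  cols <- c(before = before_color, after = after_color)

  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$beat_1based, y = .data$value, colour = .data$trace
  )) +
    ggplot2::geom_line(data = df[df$trace == "before", ], linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = cols, breaks = c("before", "after")) +
    ggplot2::labs(
      x = "beat number (original)",
      y = sprintf("heart rate [%s]", series_unit(before)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_blocks
#' @param object,x A [beat_series] or `avec_scan`.
#' @param ... Passed on to [plot_blocks()].
#' @method autoplot beat_series
#' @export
autoplot.beat_series <- function(object, ...) plot_blocks(object, ...)

#' @rdname plot_blocks
#' @method autoplot avec_scan
#' @export
autoplot.avec_scan <- function(object, ...) {
  plot_blocks(object$series, scan = object, ...)
}

#' @rdname plot_blocks
#' @export
plot.beat_series <- function(x, ...) print(plot_blocks(x, ...))
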