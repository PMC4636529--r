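#' Simulate a clean canine-like heart-rate series
#'
#' Generates beat-to-beat instantaneous HR with pronounced respiratory sinus
#' arrhythmia: each beat's rate is the baseline plus a sinusoid locked to
#' breathing plus Gaussian noise,
#' `hr_i = baseline_hr + rsa_amplitude * sin(2*pi*resp_freq*t_i + resp_phase)
#' + e_i`, where `t_i` is the elapsed time at beat `i` (the running sum of
#' the RR intervals implied by the rates already generated) and
#' `e_i ~ N(0, noise_sd)`. Values are clipped to the device range.
#'
#' The generator is a pure function of its parameters and the seed.
#'
#' @param n_beats Number of beats (default 600, roughly a staged-test
#'   segment plus recovery at canine resting rates).
#' @param baseline_hr Baseline heart rate, bpm (default 90).
#' @param rsa_amplitude Respiratory modulation amplitude, bpm (default 15 —
#'   dogs show large swings).
#' @param resp_freq Breathing frequency, Hz (default 0.4, resting-dog
#'   respiratory band).
#' @param resp_phase Breathing phase at time 0, radians.
#' @param noise_sd SD of the additive Gaussian beat-to-beat noise, bpm
#'   (default 3).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param device_range Clipping range in bpm (default [polar_device_range]).
#' @return A [beat_series] in bpm, labelled `"synthetic"`.
#' @examples
#' simulate_clean_hr(100, seed = 1)
#' @export
simulate_clean_hr <- function(n_beats = 600L, baseline_hr = 90,
                              rsa_amplitude = 15, resp_freq = 0.4,
                              resp_phase = 0, noise_sd = 3, seed = NULL,
                              device_range = polar_device_range) {
  stopifnot(n_beats >= 1, baseline_hr > 0, rsa_amplitude >= 0, resp_freq >= 0,
    noise_sd >= 0)
  if (baseline_hr - rsa_amplitude < device_range[1] ||
    baseline_hr + rsa_amplitude > device_range[2]) {
    warn("RSA amplitude reaches the device range; generated values will clip.")
  }
  if (!is.null(seed)) set.seed(seed)
  eps <- if (noise_sd > 0) rnorm(n_beats, 0, noise_sd) else numeric(n_beats)
  hr <- numeric(n_beats)
  t <- 0
  for (i in seq_len(n_beats)) {
    h <- baseline_hr + rsa_amplitude * sin(2 * pi * resp_freq * t + resp_phase) +
      eps[i]
    h <- min(max(h, device_range[1]), device_range[2])
    hr[i] <- h
    t <- t + 60 / h # seconds to the next beat
  }
  beat_series(hr, unit = "bpm", label = "synthetic",
    device_range = device_range)
}

#' Inject labelled transmission artifacts into a clean series
#'
#' Adds the three artifact types seen in chest-belt recordings, each with
#' ground-truth labels so that detection and correction can be validated:
#'
#' * `spike` — a beat's rate is replaced by `baseline +/- spike_magnitude`
#'   (bpm, sign random, clipped to the device range): the isolated extreme
#'   excursion typical of momentary electrode contact loss.
#' * `missed_beat` — two adjacent RR intervals merge into one
#'   (approximately doubled RR; series shortens by one beat): a beat the
#'   device failed to register.
#' * `extra_beat` — one RR interval splits into two halves (series
#'   lengthens by one beat): a spuriously registered beat.
#'
#' Artifact counts are Binomial draws at the given per-beat rates;
#' positions are drawn without replacement (disjoint by construction) and
#' away from the first/last few beats. Structural artifacts are applied on
#' the ms representation and spikes in bpm, matching the physical mechanism
#' of each error. Everything is reproducible from the seed.
#'
#' @param series A clean [beat_series].
#' @param spike_rate,missed_rate,extra_rate Per-beat artifact rates, each in
#'   `[0, 0.1]`.
#' @param spike_magnitude Spike excursion from baseline in bpm (default 80,
#'   the order of magnitude of real transmission spikes, which shoot towards
#'   the edges of the recordable range).
#' @param seed Integer seed.
#' @return A list of class `labeled_series`: `series` (the corrupted
#'   [beat_series], same unit as the input), `truth` (tibble `index`
#'   (0-based, in the corrupted series), `type`), and `clean` (the input).
#' @export
inject_artifacts <- function(series, spike_rate = 0, missed_rate = 0,
                             extra_rate = 0, spike_magnitude = 80,
                             seed = NULL) {
  assert_beat_series(series)
  rates <- c(spike = spike_rate, missed_beat = missed_rate,
    extra_beat = extra_rate)
  if (any(rates < 0) || any(rates > 0.1)) {
    abort("Artifact rates must lie in [0, 0.1].",
      class = "avechr_domain_error")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(series)
  counts <- vapply(rates, function(r) rbinom(1L, n, r), integer(1))
  if (sum(counts) == 0L) {
    return(structure(
      list(series = series,
        truth = tibble(index = integer(), type = character()),
        clean = series),
      class = "labeled_series"
    ))
  }
  # Disjoint, non-adjacent positions (a missed-beat merge consumes the next
  # beat too), clear of the edges. Overlapping draws are re-drawn.
  eligible <- seq.int(3L, n - 2L)
  if (2L * sum(counts) > length(eligible)) {
    abort("Artifact rates too high: positions cannot be disjoint.",
      class = "avechr_error")
  }
  pos <- sample(eligible, sum(counts))
  tries <- 0L
  while (sum(counts) > 1L && min(diff(sort(pos))) < 2L) {
    tries <- tries + 1L
    if (tries > 1000L) {
      abort("Artifact rates too high: positions cannot be disjoint.",
        class = "avechr_error")
    }
    pos <- sample(eligible, sum(counts))
  }
  type <- rep(names(counts), counts)

  bpm <- series_values(as_bpm(series))
  baseline <- median(bpm)
  dr <- attr(series, "device_range", exact = TRUE) %||% polar_device_range

  # Spikes act on the rate of a single beat.
  sp <- pos[type == "spike"]
  if (length(sp) > 0L) {
    sign <- sample(c(-1, 1), length(sp), replace = TRUE)
    bpm[sp] <- pmin(pmax(baseline + sign * spike_magnitude, dr[1]), dr[2])
  }

  # Structural artifacts act on the interval sequence; work in ms with a
  # parallel label vector, applying edits from the highest position down so
  # earlier positions stay valid.
  rr <- 60000 / bpm
  lab <- character(length(rr))
  lab[sp] <- "spike"
  struct <- data.frame(pos = pos[type != "spike"],
    type = type[type != "spike"])
  struct <- struct[order(-struct$pos), ]
  for (j in seq_len(nrow(struct))) {
    p <- struct$pos[j]
    if (struct$type[j] == "missed_beat") {
      rr[p] <- rr[p] + rr[p + 1L]
      rr <- rr[-(p + 1L)]
      lab[p] <- "missed_beat"
      lab <- lab[-(p + 1L)]
    } else {
      half <- rr[p] / 2
      rr <- append(rr, half, after = p)
      rr[p] <- half
      lab[p] <- "extra_beat"
      lab <- append(lab, "extra_beat", after = p)
    }
  }

  corrupted_bpm <- pmin(pmax(60000 / rr, dr[1]), dr[2])
  out <- beat_series(corrupted_bpm, unit = "bpm",
    label = series_label(series), device_range = dr)
  out <- convert_unit(out, series_unit(series))
  structure(
    list(
      series = out,
      truth = tibble(index = which(nzchar(lab)) - 1L,
        type = lab[nzchar(lab)]),
      clean = series
    ),
    class = "labeled_series"
  )
}

#' @export
print.labeled_series <- function(x, ...) {
  cat(sprintf(
    "Labelled synthetic series: %d beats, %d artifact(s) (%s)\n",
    nrow(x$series), nrow(x$truth),
    if (nrow(x$truth) == 0) "none" else
      paste(names(table(x$truth$type)), table(x$truth$type),
        sep = ": ", collapse = ", ")
  ))
  invisible(x)
}

#' Write a labelled synthetic recording as fixture files
#'
#' Produces the three plain-text files consumed by validation workflows: an
#' HRM export (`<stem>.hrm`), a CSV of the series (`<stem>.csv`, in the
#' series' unit) and the ground-truth labels (`<stem>_truth.csv` with
#' columns `index`, `type`).
#'
#' @param labeled A `labeled_series` from [inject_artifacts()].
#' @param dir Output directory (created if needed).
#' @param stem File-name stem.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_fixtures <- function(labeled, dir, stem = "synthetic") {
  if (!inherits(labeled, "labeled_series")) {
    abort("`labeled` must come from inject_artifacts().",
      class = "avechr_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    hrm = file.path(dir, paste0(stem, ".hrm")),
    csv = file.path(dir, paste0(stem, ".csv")),
    truth = file.path(dir, paste0(stem, "_truth.csv"))
  )
  write_hrm(labeled$series, paths[["hrm"]])
  write_beat_csv(labeled$series, paths[["csv"]])
  readr::write_csv(labeled$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}
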