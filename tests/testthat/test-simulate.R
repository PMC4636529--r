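test_that("the degenerate generator is constant at baseline and fully deterministic", {
  s <- simulate_clean_hr(50, rsa_amplitude = 0, noise_sd = 0, seed = 1)
  expect_true(all(series_values(s) == 90))

  a <- simulate_clean_hr(500, seed = 99)
  b <- simulate_clean_hr(500, seed = 99)
  expect_identical(series_values(a), series_values(b))
  expect_false(identical(
    series_values(simulate_clean_hr(500, seed = 100)),
    series_values(a)
  ))
})

test_that("mean level tracks the baseline", {
  # Without RSA the beat-averaged mean is unbiased.
  s0 <- simulate_clean_hr(2000, rsa_amplitude = 0, seed = 1)
  expect_lt(abs(mean(series_values(s0)) - 90), 2 * 3 / sqrt(2000))
  # With RSA, beats sample the sinusoid in proportion to the rate, biasing
  # the beat mean upward by about amp^2 / (2 * baseline) ~ 1.25 bpm.
  s1 <- simulate_clean_hr(2000, seed = 1)
  expect_lt(abs(mean(series_values(s1)) - 90), 15^2 / (2 * 90) + 0.3)
})

test_that("the dominant spectral peak sits at the breathing frequency", {
  s <- simulate_clean_hr(2000, seed = 10)
  hr <- series_values(s)
  sp <- stats::spec.pgram(hr - mean(hr), taper = 0, detrend = FALSE, plot = FALSE)
  peak_per_beat <- sp$freq[which.max(sp$spec)]
  # 0.4 Hz in beat-index units is 0.4 * mean RR (s/beat) cycles per beat
  target <- 0.4 * mean(60 / hr)
  expect_lt(abs(peak_per_beat - target), diff(sp$freq[1:2])) # within one bin
})

test_that("parameters that would clip at the device range warn", {
  expect_warning(simulate_clean_hr(10, baseline_hr = 25, rsa_amplitude = 15,
    seed = 1), "clip")
  expect_warning(simulate_clean_hr(10, baseline_hr = 235, rsa_amplitude = 10,
    seed = 1), "clip")
})

test_that("artifact injection is labelled, seeded, and structurally correct", {
  clean <- simulate_clean_hr(200, seed = 12)
  none <- inject_artifacts(clean, seed = 13)
  expect_identical(none$series, clean)
  expect_identical(nrow(none$truth), 0L)

  # one missed beat on a constant 600 ms series merges two intervals
  const <- beat_series(rep(600, 100), "ms")
  lab <- inject_artifacts(const, missed_rate = 0.01, seed = 50)
  n_miss <- nrow(lab$truth)
  expect_identical(nrow(lab$series), 100L - n_miss)
  rr <- series_values(lab$series)
  expect_identical(sum(abs(rr - 1200) < 1), n_miss)
  expect_true(all(abs(rr[-(lab$truth$index + 1)] - 600) < 1))

  # extra beats split an interval into two halves
  lab2 <- inject_artifacts(const, extra_rate = 0.01, seed = 51)
  n_extra <- nrow(lab2$truth) / 2 # both halves are labelled
  expect_identical(nrow(lab2$series), 100L + as.integer(n_extra))
  expect_identical(
    sum(abs(series_values(lab2$series) - 300) < 1),
    as.integer(2 * n_extra)
  )

  # truth size equals the seeded binomial draw; re-runs are identical
  big <- simulate_clean_hr(1000, seed = 14)
  l1 <- inject_artifacts(big, spike_rate = 0.01, seed = 15)
  l2 <- inject_artifacts(big, spike_rate = 0.01, seed = 15)
  expect_identical(l1$truth, l2$truth)
  expect_identical(series_values(l1$series), series_values(l2$series))
  set.seed(15)
  expect_identical(nrow(l1$truth), rbinom(1L, 1000L, 0.01))

  expect_error(inject_artifacts(clean, spike_rate = 0.5),
    class = "avechr_domain_error"
  )
})

test_that("spike magnitudes land at baseline +/- magnitude in bpm", {
  clean <- simulate_clean_hr(500, noise_sd = 0, rsa_amplitude = 0, seed = 1)
  lab <- inject_artifacts(clean, spike_rate = 0.02, spike_magnitude = 60,
    seed = 2)
  spikes <- series_values(lab$series)[lab$truth$index + 1]
  expect_true(all(abs(abs(spikes - 90) - 60) < 1e-9))
})

test_that("detection recovers injected spikes without over-flagging clean data", {
  # compact version of the full validation (more seeds in the wider suite)
  hits <- 0L
  total <- 0L
  for (seed in 1:8) {
    lab <- inject_artifacts(simulate_clean_hr(600, seed = seed),
      spike_rate = 0.01, seed = 1000 + seed
    )
    scan <- scan_series(lab$series)
    spikes <- lab$truth$index[lab$truth$type == "spike"]
    # sensitivity is assessed where the detector tests at all: edge beats
    # are reported untested, which is distinct from clean
    spikes <- spikes[tidy(scan)$tested[spikes + 1L]]
    hits <- hits + sum(spikes %in% scan$flagged_indices)
    total <- total + length(spikes)
  }
  expect_gt(total, 20L)
  expect_gte(hits / total, 0.95)

  clean_scan <- scan_series(simulate_clean_hr(600, seed = 3))
  v <- tidy(clean_scan)
  rate <- mean(v$is_outlier[v$tested])
  analytic <- 1 - gauss_error_probability(
    compute_k(solve_lambda(0.75), solve_lambda(0.75), 40)
  )
  expect_lte(rate, analytic + 0.05)
})

test_that("fixture files round-trip through the standard readers", {
  dir <- withr::local_tempdir()
  lab <- inject_artifacts(simulate_clean_hr(120, seed = 5),
    spike_rate = 0.02, seed = 6
  )
  paths <- write_fixtures(lab, dir, "fix")
  expect_true(all(file.exists(paths)))
  expect_identical(
    series_values(read_beat_csv(paths[["csv"]], unit = "bpm")),
    series_values(lab$series)
  )
  truth <- readr::read_csv(paths[["truth"]], show_col_types = FALSE)
  expect_identical(as.integer(truth$index), lab$truth$index)
})
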