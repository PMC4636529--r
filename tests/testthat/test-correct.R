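test_that("non-overlapping candidates enter the plan in series order", {
  vals <- rep(120, 200)
  vals[c(31, 151)] <- c(360, 400) # 0-based 30 and 150, > 41 beats apart
  scan <- scan_series(beat_series(vals, "bpm"))
  plan <- resolve_overlaps(scan)
  expect_identical(plan$index, c(30L, 150L))
  expect_identical(plan$step, 1:2)
})

test_that("adjacent spike pair: most extreme first, second re-tested on the recombined window", {
  # 238 then 60 bpm on a constant 120 baseline. Hand-computed from the
  # original series (k = 1.408709 at n = 40):
  #   238: window holds the 60 -> mean 118.5, s = 9.4868, priority 12.60
  #    60: window holds the 238 -> mean 122.95, s = 18.657, priority 3.37
  # After the 238 is removed the 60's re-formed window is all 120s (s = 0),
  # so it stays an outlier and is retained in the plan.
  vals <- rep(120, 120)
  vals[c(61, 62)] <- c(238, 60)
  scan <- scan_series(beat_series(vals, "bpm"))
  expect_identical(scan$flagged_indices, c(60L, 61L))
  plan <- resolve_overlaps(scan)
  expect_identical(plan$index, c(60L, 61L)) # larger deviation first
  expect_equal(plan$value, c(238, 60))
  expect_equal(plan$window_mean[1], 118.5)
  expect_equal(plan$window_sd[1], 9.4868, tolerance = 1e-4)
  expect_equal(plan$window_mean[2], 120) # re-formed, spike-free window
  expect_equal(plan$window_sd[2], 0)
})

test_that("a moderate companion next to an extreme spike is masked at scan time", {
  # 238 then 102 bpm on a 120 baseline: the 238 inflates the companion's
  # window SD to 18.66, so |102 - 122.95| = 20.95 < k*s = 26.28 and the 102
  # never becomes a candidate -- the situation the visual pass is for.
  vals <- rep(120, 120)
  vals[c(61, 62)] <- c(238, 102)
  scan <- scan_series(beat_series(vals, "bpm"))
  expect_identical(scan$flagged_indices, 60L)
  plan <- resolve_overlaps(scan)
  expect_identical(plan$index, 60L) # plan of length 1
})

test_that("re-testing drops candidates explained by a more extreme neighbour", {
  # Two moderate excursions close together, each pushed over threshold
  # mostly by the other's inflation of the window mean/SD; after the more
  # extreme one is removed the other may be retained or dropped, but the
  # plan can never grow beyond the flagged set.
  vals <- rep(120, 120)
  vals[c(61, 63)] <- c(360, 170)
  scan <- scan_series(beat_series(vals, "bpm"))
  plan <- resolve_overlaps(scan)
  expect_true(all(plan$index %in% scan$flagged_indices))
  expect_identical(plan$index[1], 60L) # the 360 leads
})

test_that("deletion removes exactly the planned beats and preserves order", {
  s <- beat_series(seq(100, 199), "bpm")
  res <- apply_corrections(s, tibble::tibble(index = 10L), "delete")
  expect_identical(nrow(res$series), 99L)
  expect_identical(series_values(res$series), c(100:109, 111:199) + 0)
  expect_identical(res$series$beat, setdiff(0:99, 10L))
  expect_identical(replay_log(s, res$log), res$series)
})

test_that("empty plans are the identity", {
  s <- simulate_clean_hr(100, seed = 2)
  res <- apply_corrections(s, tibble::tibble(index = integer()), "delete")
  expect_identical(res$series, s)
  expect_identical(nrow(res$log), 0L)
})

test_that("mean replacement uses the 5 surviving neighbours on each side", {
  s <- beat_series(1:100, "ms") # value = 1-based position
  res <- apply_corrections(s, tibble::tibble(index = 49L), "replace_mean")
  # value 50 replaced by mean(45..49, 51..55) = 50
  expect_equal(series_values(res$series)[50], 50)
  expect_identical(nrow(res$series), 100L)

  # planned neighbours are skipped: replacing values 49 and 50 together,
  # both draw on the survivors 44..48 and 51..55
  res2 <- apply_corrections(s, tibble::tibble(index = c(48L, 49L)), "replace_mean")
  expect_equal(series_values(res2$series)[49], mean(c(44:48, 51:55)))
  expect_equal(series_values(res2$series)[50], mean(c(44:48, 51:55)))

  # near a boundary at least 3 neighbours per side are required
  expect_error(
    apply_corrections(s, tibble::tibble(index = 1L), "replace_mean"),
    class = "avechr_context_error"
  )
  # but 3-4 available neighbours are accepted
  res3 <- apply_corrections(s, tibble::tibble(index = 3L), "replace_mean")
  expect_equal(series_values(res3$series)[4], mean(c(1:3, 5:9)))
})

test_that("no strategy can insert values or shift time", {
  set.seed(77)
  for (rep in 1:20) {
    s <- simulate_clean_hr(80, seed = rep)
    idx <- sort(sample(6:73, sample(0:6, 1)))
    plan <- tibble::tibble(index = idx)
    del <- apply_corrections(s, plan, "delete")
    expect_identical(nrow(del$series), 80L - length(idx))
    expect_identical(
      series_values(del$series),
      series_values(s)[setdiff(1:80, idx + 1)]
    )
    rep_ <- apply_corrections(s, plan, "replace_mean")
    expect_identical(nrow(rep_$series), 80L)
    untouched <- setdiff(1:80, idx + 1)
    expect_identical(
      series_values(rep_$series)[untouched],
      series_values(s)[untouched]
    )
    expect_identical(replay_log(s, del$log), del$series)
    expect_identical(replay_log(s, rep_$log), rep_$series)
  }
})

test_that("correcting a clean series returns it unchanged", {
  s <- constant_series(100, 110)
  res <- correct_series(s)
  expect_identical(series_values(res$series), series_values(s))
  expect_identical(nrow(res$log), 0L)
  expect_false(res$exclusion$excluded)
})

test_that("the full workflow combines visual and algorithmic edits into one replayable log", {
  vals <- rep(120, 150)
  vals[c(31, 32)] <- c(238, 102) # visual pair
  vals[101] <- 360 # algorithmic spike
  s <- beat_series(vals, "bpm")
  res <- correct_series(s, manual_edits = tibble::tibble(index = c(30L, 31L)))
  expect_identical(sort(res$log$index), c(30L, 31L, 100L))
  expect_identical(res$log$method, c("visual", "visual", "algorithm"))
  expect_identical(replay_log(s, res$log), res$series)
  expect_identical(nrow(res$series), 147L)
})
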