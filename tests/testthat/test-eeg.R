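test_that("preprocessing notches mains and preserves the SWD band", {
  fs <- 1024
  t <- seq(0, 10, by = 1 / fs)
  out50 <- preprocess_eeg(eeg_trace(sin(2 * pi * 50 * t), fs))
  expect_lt(sd(out50$samples) / sd(sin(2 * pi * 50 * t)), 0.03)

  out8 <- preprocess_eeg(eeg_trace(sin(2 * pi * 8 * t), fs))
  expect_equal(sd(out8$samples) / sd(sin(2 * pi * 8 * t)), 1, tolerance = 0.05)

  dc <- preprocess_eeg(eeg_trace(rep(100, length(t)), fs))
  expect_lt(max(abs(dc$samples)), 1)

  expect_error(preprocess_eeg(eeg_trace(t, fs = 150)), "sampling rate")
})

test_that("interval merging and duration filtering follow the seizure rules", {
  iv <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(start = m[, 1], end = m[, 2])
  }
  expect_equal(merge_and_filter(iv(0, 3, 3.5, 6)), iv(0, 6))       # gap 0.5 < 1
  expect_equal(nrow(merge_and_filter(iv(0, 1.5))), 0)              # < 2 s
  expect_equal(merge_and_filter(iv(0, 2)), iv(0, 2))               # inclusive
  expect_equal(merge_and_filter(iv(0, 3, 4.5, 7)), iv(0, 3, 4.5, 7)) # gap 1.5
  # idempotence on random instances
  set.seed(11)
  for (k in 1:20) {
    s <- sort(runif(6, 0, 60))
    raw <- iv(s[1], s[2], s[3], s[4], s[5], s[6])
    once <- merge_and_filter(raw)
    expect_identical(merge_and_filter(once), once)
  }
  expect_error(merge_and_filter(iv(5, 6, 0, 3)), "sorted")
})

test_that("overlap fraction is the clipped intersection over block length", {
  blk <- list(onset = 10, duration = 6)
  expect_equal(overlap_fraction(blk, list(start = 20, end = 30)), 0)
  expect_equal(overlap_fraction(blk, list(start = 8, end = 20)), 1)
  expect_equal(overlap_fraction(blk, list(start = 12, end = 30)), 4 / 6)
})

test_that("stimulation blocks receive the taxonomy labels with precedence", {
  sz <- function(s, e) data.frame(start = s, end = e)
  lab <- function(bl, se) as.character(
    classify_stimulations(data.frame(onset = bl[1], duration = bl[2] - bl[1]),
                          se)$label)
  expect_equal(lab(c(10, 16), sz(8, 20)), "fully_inside")
  expect_equal(lab(c(10, 16), sz(5, 11)), "ended_seizure")
  expect_equal(lab(c(10, 16), sz(12, 30)), "started_before_mostly_inside")
  expect_equal(lab(c(10, 16), sz(14, 30)), "started_before_mostly_outside")
  expect_equal(lab(c(10, 16), sz(5, 14)), "started_during_mostly_inside")
  expect_equal(lab(c(10, 16), sz(5, 12.5)), "started_during_mostly_outside")
  expect_equal(lab(c(10, 16), sz(5, 9)), "right_after_seizure")
  expect_equal(lab(c(10, 16), sz(5, 7)), "baseline")
  # exact 50% overlap goes to the outside branch
  expect_equal(lab(c(10, 16), sz(13, 30)), "started_before_mostly_outside")
  expect_error(classify_stimulations(
    data.frame(onset = c(0, 3), duration = 6), sz(50, 60)), "overlap")
})

test_that("classification is a total partition over random configurations", {
  set.seed(99)
  levels8 <- c("baseline", "fully_inside", "started_during_mostly_inside",
               "started_during_mostly_outside", "started_before_mostly_inside",
               "started_before_mostly_outside", "ended_seizure",
               "right_after_seizure")
  for (k in 1:1000) {
    n_sz <- sample(0:3, 1)
    sz <- if (n_sz == 0) empty_intervals else {
      s <- sort(runif(2 * n_sz, 0, 200))
      merge_and_filter(data.frame(start = s[seq(1, by = 2, length.out = n_sz)],
                                  end = s[seq(2, by = 2, length.out = n_sz)]),
                       merge_gap = 1, min_duration = 0.5)
    }
    onsets <- sort(runif(3, 0, 200))
    onsets <- onsets[c(TRUE, diff(onsets) > 6)]
    out <- classify_stimulations(data.frame(onset = onsets, duration = 6), sz)
    expect_false(any(is.na(out$label)))
    expect_true(all(as.character(out$label) %in% levels8))
  }
})

test_that("generated spike-and-wave epochs are recovered exactly", {
  truth <- data.frame(start = c(20, 42), end = c(26, 47))
  for (s in 1:3) {
    ee <- make_eeg(duration = 70, seizure_schedule = truth, seed = s)
    det <- detect_swd(preprocess_eeg(ee$trace))
    expect_equal(nrow(det), 2)
    expect_lt(max(abs(det$start - truth$start)), 0.26)
    expect_lt(max(abs(det$end - truth$end)), 0.26)
    expect_true(all(det$end - det$start >= 2))
  }
})

test_that("an epoch at exactly twice baseline amplitude is detected", {
  ee <- make_eeg(duration = 60, seizure_schedule = data.frame(start = 25, end = 31),
                 amp_ratio = 2, seed = 4)
  det <- detect_swd(preprocess_eeg(ee$trace))
  expect_equal(nrow(det), 1)
})

test_that("pink-noise-only traces yield no detections in at least 9 of 10 runs", {
  fp <- vapply(1:10, function(s)
    nrow(detect_swd(preprocess_eeg(make_eeg(45, seed = 100 + s)$trace))), 0L)
  expect_gte(sum(fp == 0), 9)
})

test_that("no detected interval is ever shorter than the minimum duration", {
  for (s in 1:5) {
    sched <- data.frame(start = c(15, 30), end = c(15 + runif(1, 0.5, 4), 36))
    ee <- make_eeg(60, seizure_schedule = sched, seed = 200 + s)
    det <- detect_swd(preprocess_eeg(ee$trace))
    if (nrow(det)) expect_true(all(det$end - det$start >= 2))
  }
})

test_that("a constant trace produces no detections", {
  tr <- eeg_trace(rep(0, 1024 * 12), 1024)
  expect_equal(nrow(detect_swd(tr)), 0)
})
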