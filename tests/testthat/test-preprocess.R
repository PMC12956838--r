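test_that("baseline normalization maps baseline to exactly 100", {
  raw <- raw_pupil_trace("p1", "s1", c(4, 4.8, 4), baseline = 4)
  tr <- normalize_to_baseline(raw)
  expect_equal(tr$d_ratio, c(100, 120, 100))
  expect_error(raw_pupil_trace("p1", "s1", 1:3, baseline = 0), "positive")
})

test_that("jump rule marks from the >10% frame until return within 5%", {
  tr <- make_trace(c(100, 100, 115, 115, 104, 100))
  out <- mark_jump_artifacts(tr)
  expect_equal(which(out$missing_mask), c(3L, 4L))
  expect_equal(out$gaps$start_frame, 3L)
  expect_equal(out$gaps$end_frame, 4L)
  expect_equal(out$gaps$cause, "jump")

  # 9% step: below the start threshold, nothing marked
  below <- mark_jump_artifacts(make_trace(c(100, 109, 109, 109)))
  expect_false(any(below$missing_mask))

  constant <- mark_jump_artifacts(make_trace(rep(100, 50)))
  expect_false(any(constant$missing_mask))
})

test_that("jump rule measures the interval end against the last accepted frame", {
  # 106 is 6% from reference 100: still inside the artifact interval even
  # though it is close to the previous (artifactual) frame
  tr <- make_trace(c(100, 112, 106, 104, 100))
  out <- mark_jump_artifacts(tr)
  expect_equal(which(out$missing_mask), c(2L, 3L))
})

test_that("range rule uses strict inequalities at 40 and 160", {
  tr <- make_trace(c(100, 39.9, 40, 160, 160.1, 100))
  out <- mark_range_violations(tr)
  expect_equal(which(out$missing_mask), c(2L, 5L))

  runs <- mark_range_violations(make_trace(c(100, rep(30, 5), 100)))
  expect_equal(runs$gaps$length, 5L)
  expect_equal(runs$gaps$cause, "range")

  ok <- mark_range_violations(make_trace(seq(40, 160, length.out = 20)))
  expect_false(any(ok$missing_mask))
})

test_that("gaps of 30 frames interpolate; 31 frames exclude", {
  base <- rep(100, 360)
  tr30 <- make_trace(base)
  tr30$missing_mask[101:130] <- TRUE
  out30 <- interpolate_gaps(tr30)
  expect_true(out30$valid)
  expect_false(any(out30$missing_mask))

  tr31 <- make_trace(base)
  tr31$missing_mask[101:131] <- TRUE
  expect_false(interpolate_gaps(tr31)$valid)
})

test_that("boundary gaps without an anchor exclude the trial", {
  tr <- make_trace(rep(100, 100))
  tr$missing_mask[1:5] <- TRUE
  expect_false(interpolate_gaps(tr)$valid)
  tr2 <- make_trace(rep(100, 100))
  tr2$missing_mask[96:100] <- TRUE
  expect_false(interpolate_gaps(tr2)$valid)
})

test_that("PCHIP interpolation passes through anchors without overshoot", {
  # constant anchors -> constant fill
  tr <- make_trace(c(rep(80, 10), rep(NA, 5), rep(80, 10)))
  tr$d_ratio[is.na(tr$d_ratio)] <- 0
  tr$missing_mask[11:15] <- TRUE
  out <- interpolate_gaps(tr)
  expect_equal(out$d_ratio, rep(80, 25))

  # monotone anchors: filled values stay inside the anchor range
  withr::with_seed(42, {
    for (rep_i in 1:100) {
      n <- 40
      anchors <- sort(runif(n, 60, 140))
      gap_start <- sample(5:(n - 10), 1)
      gap_len <- sample(1:5, 1)
      tr <- make_trace(anchors)
      tr$missing_mask[gap_start:(gap_start + gap_len - 1)] <- TRUE
      out <- interpolate_gaps(tr)
      filled <- out$d_ratio[gap_start:(gap_start + gap_len - 1)]
      lo <- anchors[gap_start - 1]
      hi <- anchors[gap_start + gap_len]
      expect_true(all(filled >= lo - 1e-9 & filled <= hi + 1e-9))
      # anchors themselves are untouched
      expect_equal(out$d_ratio[-(gap_start:(gap_start + gap_len - 1))],
                   anchors[-(gap_start:(gap_start + gap_len - 1))])
    }
  })
})

test_that("preprocessing is idempotent on cleaned traces", {
  cfg <- generator_config(n_participants = 1L, n_positive = 3L,
                          n_negative = 3L)
  ds <- generate_dataset(cfg)
  pp <- preprocess_dataset(ds$trials)
  for (tr in pp$valid) {
    again <- mark_jump_artifacts(
      mark_range_violations(
        pupil_trace(tr$participant_id, tr$stimulus_id, tr$d_ratio)
      )
    )
    again <- interpolate_gaps(again)
    expect_true(again$valid)
    expect_equal(again$d_ratio, tr$d_ratio)
  }
})

test_that("clean traces survive preprocessing unchanged", {
  d <- generate_clean_trace(waveform_params(18, 50, 80, 103), 360)
  raw <- raw_pupil_trace("p1", "s1", d * 4 / 100, baseline = 4)
  out <- preprocess_trial(raw)
  expect_true(out$valid)
  expect_equal(out$d_ratio, d, tolerance = 1e-9)
})

test_that("every excluded trial has an over-long or unanchored gap", {
  cfg <- generator_config(n_participants = 3L)
  ds <- generate_dataset(cfg)
  pp <- preprocess_dataset(ds$trials)
  excluded <- pp$traces[!vapply(pp$traces, function(x) x$valid, logical(1))]
  expect_gt(length(excluded), 0)
  for (tr in excluded) {
    n <- length(tr$d_ratio)
    runs <- rle(tr$missing_mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    bad <- runs$values & (runs$lengths > 30 | starts == 1L | ends == n)
    expect_true(any(bad))
  }
})

test_that("dataset preprocessing counts are reproducible", {
  cfg <- generator_config(n_participants = 3L)
  s1 <- preprocess_dataset(generate_dataset(cfg)$trials)$summary
  s2 <- preprocess_dataset(generate_dataset(cfg)$trials)$summary
  expect_identical(s1, s2)
  expect_equal(s1$n_trials, 150)
})
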