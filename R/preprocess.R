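#' Normalize a raw trace to its individual baseline
#'
#' Converts raw pupil diameters into relative pupil sizes (D_RATIO) on a
#' scale where the participant's baseline diameter equals 100:
#' `d_ratio[t] = 100 * values[t] / baseline`.
#'
#' @param raw a [raw_pupil_trace()].
#' @return A [pupil_trace()] with an all-false missing mask.
#' @export
normalize_to_baseline <- function(raw) {
  if (!inherits(raw, "raw_pupil_trace")) stop("`raw` must be a raw_pupil_trace")
  if (raw$baseline <= 0) stop("baseline must be positive")
  pupil_trace(raw$participant_id, raw$stimulus_id,
              100 * raw$values / raw$baseline)
}

#' Mark abrupt frame-to-frame jump artifacts
#'
#' Scans frames in order keeping a reference `r`, the D_RATIO of the last
#' accepted frame. When a frame deviates from `r` by more than
#' `start_pct`% it opens a missing interval; subsequent frames stay
#' missing until the first frame back within `end_pct`% of the same
#' reference, which is retained and becomes the new reference. Frames
#' already missing are skipped (they never update the reference).
#'
#' @param trace a normalized [pupil_trace()].
#' @param start_pct percent change opening an interval (default 10).
#' @param end_pct percent change closing it (default 5).
#' @return The trace with an updated missing mask and one `"jump"` gap
#'   record per marked run appended to `$gaps`.
#' @export
mark_jump_artifacts <- function(trace, start_pct = 10, end_pct = 5) {
  d <- trace$d_ratio
  miss <- trace$missing_mask
  n <- length(d)
  new_gaps <- empty_gap_records()
  # establish the initial reference: first non-missing frame
  first_ok <- which(!miss)[1]
  if (is.na(first_ok)) return(trace)
  r <- d[first_ok]
  in_gap <- FALSE
  gap_start <- NA_integer_
  t <- first_ok + 1L
  while (t <= n) {
    if (miss[t]) {
      t <- t + 1L
      next
    }
    rel <- abs(d[t] - r) / r * 100
    if (!in_gap) {
      if (rel > start_pct) {
        in_gap <- TRUE
        gap_start <- t
        miss[t] <- TRUE
      } else {
        r <- d[t]
      }
    } else {
      if (rel <= end_pct) {
        # frame t is retained and closes the interval at t - 1
        new_gaps <- dplyr::bind_rows(
          new_gaps, gap_record(gap_start, t - 1L, "jump")
        )
        in_gap <- FALSE
        r <- d[t]
      } else {
        miss[t] <- TRUE
      }
    }
    t <- t + 1L
  }
  if (in_gap) {
    new_gaps <- dplyr::bind_rows(new_gaps, gap_record(gap_start, n, "jump"))
  }
  trace$missing_mask <- miss
  trace$gaps <- dplyr::bind_rows(trace$gaps, new_gaps)
  trace
}

#' Mark frames outside the physiological D_RATIO range
#'
#' Every frame with D_RATIO strictly below `low` or strictly above `high`
#' is marked missing (the bounds themselves are retained); contiguous
#' marked runs become `"range"` gap records.
#'
#' @param trace a normalized [pupil_trace()].
#' @param low,high absolute D_RATIO bounds (defaults 40 / 160).
#' @return The trace with an updated missing mask and gap records.
#' @export
mark_range_violations <- function(trace, low = 40, high = 160) {
  d <- trace$d_ratio
  bad <- !trace$missing_mask & (d < low | d > high)
  if (any(bad)) {
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      trace$gaps <- dplyr::bind_rows(
        trace$gaps, gap_record(starts[i], ends[i], "range")
      )
    }
    trace$missing_mask <- trace$missing_mask | bad
  }
  trace
}

#' Fill short missing intervals by shape-preserving interpolation
#'
#' Missing runs of `max_gap` frames or fewer that are anchored by
#' non-missing frames on both sides are filled with PCHIP (piecewise cubic
#' Hermite) interpolation through all non-missing frames. Any run longer
#' than `max_gap`, or touching the first or last frame (no anchor on one
#' side), invalidates the trial instead of being extrapolated.
#'
#' @param trace a [pupil_trace()] with its missing mask populated.
#' @param max_gap longest interpolatable run (default 30 frames, twice the
#'   ~250 ms minimum latency of stimulus-driven pupil change at 60 fps).
#' @return The trace; if it remains valid it has no missing frames.
#' @export
interpolate_gaps <- function(trace, max_gap = 30) {
  miss <- trace$missing_mask
  n <- length(miss)
  if (!any(miss)) return(trace)
  runs <- rle(miss)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in which(runs$values)) {
    len <- runs$lengths[i]
    boundary <- starts[i] == 1L || ends[i] == n
    if (len > max_gap || boundary) {
      trace$valid <- FALSE
      return(trace)
    }
  }
  anchors <- which(!miss)
  if (length(anchors) < 2) {
    trace$valid <- FALSE
    return(trace)
  }
  holes <- which(miss)
  trace$d_ratio[holes] <- pracma::pchip(
    anchors, trace$d_ratio[anchors], holes
  )
  trace$missing_mask[holes] <- FALSE
  trace
}

#' Clean one trial: normalize, mark artifacts, interpolate, flag validity
#'
#' Applies the full cleaning sequence: baseline normalization, the
#' frame-to-frame jump rule followed by interpolation, then the absolute
#' range rule followed by interpolation. A trial is excluded (valid =
#' FALSE) as soon as any missing run exceeds `max_gap_frames` or touches
#' the trace boundary without an anchor.
#'
#' @param raw a [raw_pupil_trace()].
#' @param config a [run_config()].
#' @return A cleaned [pupil_trace()].
#' @export
preprocess_trial <- function(raw, config = run_config()) {
  tr <- normalize_to_baseline(raw)
  tr <- mark_jump_artifacts(tr, config$jump_start_pct, config$jump_end_pct)
  tr <- interpolate_gaps(tr, config$max_gap_frames)
  if (!tr$valid) return(tr)
  tr <- mark_range_violations(tr, config$d_ratio_low, config$d_ratio_high)
  tr <- interpolate_gaps(tr, config$max_gap_frames)
  tr
}

#' Clean a whole dataset of trials
#'
#' @param raws list of [raw_pupil_trace()] objects.
#' @param config a [run_config()].
#' @return A list with `traces` (all cleaned traces), `valid` (the valid
#'   subset) and `summary` (counts of kept / excluded trials).
#' @export
preprocess_dataset <- function(raws, config = run_config()) {
  traces <- lapply(raws, preprocess_trial, config = config)
  is_valid <- vapply(traces, function(x) x$valid, logical(1))
  list(
    traces = traces,
    valid = traces[is_valid],
    summary = tibble::tibble(
      n_trials = length(traces),
      n_valid = sum(is_valid),
      n_excluded = sum(!is_valid)
    )
  )
}
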