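#' The 45 pupil-response feature names
#'
#' Point-based summary statistics, latency/ratio descriptors of the
#' constriction-then-recovery waveform, the area under the pupil curve
#' (AUPC) over the full trial and over six 60-frame intervals, the sum of
#' absolute frame-to-frame changes over the same windows, and
#' start-normalized (`s_`) variants of the cumulative features computed
#' after rescaling the trace so its first frame equals 100.
#'
#' @return Character vector of length 45, in canonical column order.
#' @export
feature_names <- function() {
  c(
    "max", "min", "mean", "std", "start", "finish",
    "peak", "peak_ratio", "peak_latency", "drop_latency",
    "drop_ratio", "recovery_ratio", "response_duration", "reaction_extent",
    "stability", "range", "baseline_deviation",
    "aupc", "s_aupc",
    paste0("aupc", 1:6), paste0("s_aupc", 1:6),
    "change_sum", "s_change_sum",
    paste0("change_sum", 1:6), paste0("s_change_sum", 1:6)
  )
}

#' Interval scheme used by the windowed features
#'
#' The trial is partitioned into 6 equal windows (frames 1–60, 61–120,
#' ..., 301–360 for a 360-frame trial). The frame-to-frame difference that
#' crosses a window boundary is assigned to the later window, so the six
#' windowed change sums partition the total change sum exactly.
#'
#' @param frames_per_trial total frames (must be divisible by 6).
#' @return tibble with `interval`, `start_frame`, `end_frame`.
#' @export
interval_scheme <- function(frames_per_trial = 360) {
  if (frames_per_trial %% 6 != 0) {
    stop("`frames_per_trial` must be divisible by 6")
  }
  len <- frames_per_trial / 6
  tibble::tibble(
    interval = 1:6,
    start_frame = as.integer((0:5) * len + 1),
    end_frame = as.integer((1:6) * len)
  )
}

#' Extract the 45 waveform features from one valid trace
#'
#' Conventions: latencies are 1-based frame indices from stimulus onset;
#' ties for extrema resolve to the earliest frame; `peak` is the maximum
#' after frame 50 (frames 51..end); `std` is the population standard
#' deviation; AUPC is the plain sum of per-frame D_RATIO values
#' (rectangle rule with unit frame spacing); the three "compared to"
#' descriptors are ratios (`peak/min`, `min/start`, `finish/start`).
#'
#' @param trace a valid, fully interpolated [pupil_trace()].
#' @return Named numeric vector of length 45.
#' @export
extract_features <- function(trace) {
  if (!isTRUE(trace$valid)) stop("trace is flagged invalid; cannot extract")
  d <- trace$d_ratio
  n <- length(d)
  if (any(!is.finite(d))) stop("trace contains non-finite values")
  if (d[1] <= 0) stop("start value must be positive")
  mean_v <- mean(d)
  std_v <- sqrt(mean((d - mean_v)^2)) # population sd
  if (std_v == 0) {
    stop("constant trace: stability (mean/std) undefined; ",
         "trial excluded from feature extraction")
  }
  max_v <- max(d)
  min_v <- min(d)
  start_v <- d[1]
  finish_v <- d[n]
  post <- d[51:n]
  peak_v <- max(post)
  peak_latency <- 50 + which.max(post) # earliest attaining frame, 1-based
  drop_latency <- which.min(d)
  sch <- interval_scheme(n)
  d_s <- d * 100 / start_v
  diffs <- abs(diff(d))   # diffs[t-1] = |d[t] - d[t-1]|, assigned to frame t
  diffs_s <- abs(diff(d_s))
  aupc_i <- vapply(1:6, function(i) {
    sum(d[sch$start_frame[i]:sch$end_frame[i]])
  }, numeric(1))
  s_aupc_i <- vapply(1:6, function(i) {
    sum(d_s[sch$start_frame[i]:sch$end_frame[i]])
  }, numeric(1))
  # the boundary-crossing difference |d[start] - d[start-1]| belongs to the
  # later interval: frame t's difference lands in the interval containing t
  change_i <- vapply(1:6, function(i) {
    lo <- max(sch$start_frame[i], 2L)
    sum(diffs[(lo - 1L):(sch$end_frame[i] - 1L)])
  }, numeric(1))
  s_change_i <- vapply(1:6, function(i) {
    lo <- max(sch$start_frame[i], 2L)
    sum(diffs_s[(lo - 1L):(sch$end_frame[i] - 1L)])
  }, numeric(1))
  out <- c(
    max = max_v, min = min_v, mean = mean_v, std = std_v,
    start = start_v, finish = finish_v,
    peak = peak_v, peak_ratio = peak_v / min_v,
    peak_latency = peak_latency, drop_latency = drop_latency,
    drop_ratio = min_v / start_v, recovery_ratio = finish_v / start_v,
    response_duration = peak_latency - drop_latency,
    reaction_extent = min_v / start_v + finish_v / start_v,
    stability = mean_v / std_v, range = max_v - min_v,
    baseline_deviation = start_v - mean_v,
    aupc = sum(d), s_aupc = sum(d_s),
    setNames(aupc_i, paste0("aupc", 1:6)),
    setNames(s_aupc_i, paste0("s_aupc", 1:6)),
    change_sum = sum(diffs), s_change_sum = sum(diffs_s),
    setNames(change_i, paste0("change_sum", 1:6)),
    setNames(s_change_i, paste0("s_change_sum", 1:6))
  )
  out[feature_names()]
}

#' Build the classification feature table
#'
#' Extracts features from every valid trace and joins the stimulus
#' metadata (valence label, arousal and spatial-frequency levels). Traces
#' whose extraction fails (constant trace, non-finite values) are dropped
#' and reported in the `exclusions` attribute, mirroring the exclusion of
#' trials with feature-specific missing values.
#'
#' @param traces list of valid [pupil_trace()] objects.
#' @param metadata stimulus metadata tibble covering all stimulus ids.
#' @return tibble with keys, 45 feature columns and metadata columns;
#'   attribute `exclusions` lists dropped trials and reasons.
#' @export
extract_feature_table <- function(traces, metadata) {
  stim_ids <- vapply(traces, function(x) x$stimulus_id, character(1))
  unknown <- setdiff(unique(stim_ids), metadata$stimulus_id)
  if (length(unknown) > 0) {
    stop("stimulus id(s) absent from metadata: ",
         paste(unknown, collapse = ", "))
  }
  rows <- vector("list", length(traces))
  excl <- list()
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    fv <- tryCatch(extract_features(tr), error = function(e) e)
    if (inherits(fv, "error")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        participant_id = tr$participant_id,
        stimulus_id = tr$stimulus_id,
        reason = conditionMessage(fv)
      )
      next
    }
    rows[[i]] <- tibble::tibble(
      participant_id = tr$participant_id,
      stimulus_id = tr$stimulus_id,
      !!!as.list(fv)
    )
  }
  tab <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (nrow(tab) > 0) {
    tab <- dplyr::left_join(tab, metadata, by = "stimulus_id")
  }
  attr(tab, "exclusions") <- dplyr::bind_rows(excl)
  tab
}
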