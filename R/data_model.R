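#' Construct a raw pupil trace
#'
#' A raw trace holds one trial's pupil diameters in device units together
#' with the participant-specific baseline diameter that defines the
#' individual reference (a frame equal to `baseline` maps to a relative
#' pupil size, D_RATIO, of exactly 100 after normalization).
#'
#' @param participant_id character scalar.
#' @param stimulus_id character scalar.
#' @param values numeric vector of raw pupil diameters, one per frame.
#' @param baseline positive scalar, the participant's reference diameter.
#' @param sampling_rate frames per second (default 60).
#' @return An object of class `raw_pupil_trace`.
#' @export
raw_pupil_trace <- function(participant_id, stimulus_id, values, baseline,
                            sampling_rate = 60) {
  stopifnot(length(participant_id) == 1, length(stimulus_id) == 1)
  if (!is.numeric(values) || length(values) < 1) {
    stop("`values` must be a non-empty numeric vector")
  }
  if (!is.numeric(baseline) || length(baseline) != 1 || !is.finite(baseline) ||
      baseline <= 0) {
    stop("`baseline` must be a single positive finite number")
  }
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive")
  structure(
    list(
      participant_id = as.character(participant_id),
      stimulus_id = as.character(stimulus_id),
      sampling_rate = sampling_rate,
      values = as.numeric(values),
      baseline = as.numeric(baseline)
    ),
    class = "raw_pupil_trace"
  )
}

#' Construct a normalized pupil trace
#'
#' Holds a baseline-normalized D_RATIO series (baseline = 100) with a
#' per-frame missing mask, a validity flag and the gap records accumulated
#' during preprocessing.
#'
#' @param participant_id,stimulus_id identifiers.
#' @param d_ratio numeric vector of relative pupil sizes.
#' @param missing_mask logical vector, same length as `d_ratio`.
#' @param valid logical exclusion flag.
#' @param gaps tibble of gap records (see [gap_record()]).
#' @return An object of class `pupil_trace`.
#' @export
pupil_trace <- function(participant_id, stimulus_id, d_ratio,
                        missing_mask = rep(FALSE, length(d_ratio)),
                        valid = TRUE, gaps = empty_gap_records()) {
  if (length(d_ratio) != length(missing_mask)) {
    stop("`d_ratio` and `missing_mask` must have the same length")
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      stimulus_id = as.character(stimulus_id),
      d_ratio = as.numeric(d_ratio),
      missing_mask = as.logical(missing_mask),
      valid = isTRUE(valid),
      gaps = gaps
    ),
    class = "pupil_trace"
  )
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf(
    "<pupil_trace> %s / %s: %d frames, %d missing, valid = %s\n",
    x$participant_id, x$stimulus_id, length(x$d_ratio),
    sum(x$missing_mask), x$valid
  ))
  invisible(x)
}

#' @export
print.raw_pupil_trace <- function(x, ...) {
  cat(sprintf(
    "<raw_pupil_trace> %s / %s: %d frames @ %g fps, baseline %.3g\n",
    x$participant_id, x$stimulus_id, length(x$values), x$sampling_rate,
    x$baseline
  ))
  invisible(x)
}

#' One contiguous run of artifact-marked frames
#'
#' Frames are 1-based and both endpoints are inclusive.
#'
#' @param start_frame,end_frame 1-based inclusive frame indices.
#' @param cause `"jump"` (frame-to-frame change rule) or `"range"`
#'   (absolute D_RATIO bounds rule).
#' @return One-row tibble.
#' @export
gap_record <- function(start_frame, end_frame, cause) {
  stopifnot(end_frame >= start_frame, cause %in% c("jump", "range"))
  tibble::tibble(
    start_frame = as.integer(start_frame),
    end_frame = as.integer(end_frame),
    length = as.integer(end_frame - start_frame + 1L),
    cause = cause
  )
}

#' @rdname gap_record
#' @export
empty_gap_records <- function() {
  tibble::tibble(
    start_frame = integer(), end_frame = integer(),
    length = integer(), cause = character()
  )
}

#' Read pupil trials from a long-format CSV
#'
#' The canonical trace format is long: one row per frame with columns
#' `participant_id`, `stimulus_id`, `frame`, `value`, `baseline`. Frames
#' must be contiguous (1, 2, ..., n) within each trial.
#'
#' @param path path to a CSV file.
#' @return A list of [raw_pupil_trace()] objects, one per
#'   (participant, stimulus) pair.
#' @export
read_trials <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("participant_id", "stimulus_id", "frame", "value", "baseline")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("trials CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- dplyr::arrange(df, .data$participant_id, .data$stimulus_id,
                       .data$frame)
  keys <- paste(df$participant_id, df$stimulus_id, sep = "\r")
  split_idx <- split(seq_len(nrow(df)), factor(keys, levels = unique(keys)))
  lapply(split_idx, function(idx) {
    sub <- df[idx, ]
    if (!identical(as.integer(sub$frame), seq_len(nrow(sub)))) {
      stop(sprintf(
        "non-contiguous frames for trial %s / %s",
        sub$participant_id[1], sub$stimulus_id[1]
      ))
    }
    bl <- unique(sub$baseline)
    if (length(bl) != 1) {
      stop(sprintf("trial %s / %s has a non-constant baseline column",
                   sub$participant_id[1], sub$stimulus_id[1]))
    }
    raw_pupil_trace(sub$participant_id[1], sub$stimulus_id[1],
                    sub$value, bl)
  })
}

#' Write pupil trials to the long CSV format
#'
#' @param traces list of [raw_pupil_trace()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(traces, path) {
  rows <- purrr::map_dfr(traces, function(tr) {
    tibble::tibble(
      participant_id = tr$participant_id,
      stimulus_id = tr$stimulus_id,
      frame = seq_along(tr$values),
      value = tr$values,
      baseline = tr$baseline
    )
  })
  con <- file(path, "w")
  writeLines("# frame indices are 1-based; frame 1 = stimulus onset", con)
  close(con)
  readr::write_csv(rows, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a feature table to CSV
#'
#' All rows must carry the full 45-feature set (see [feature_names()]) and
#' every feature value must be finite; rows that failed extraction should
#' have been dropped upstream, not serialized.
#'
#' @param rows tibble with `participant_id`, `stimulus_id` and the 45
#'   feature columns (extra metadata columns are allowed and preserved).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(rows, path) {
  needed <- c("participant_id", "stimulus_id", feature_names())
  missing_cols <- setdiff(needed, names(rows))
  if (length(missing_cols) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  feats <- as.matrix(rows[, feature_names()])
  if (nrow(rows) > 0 && !all(is.finite(feats))) {
    stop("feature table contains non-finite values; drop such rows first")
  }
  con <- file(path, "w")
  writeLines("# latencies and frame indices are 1-based", con)
  close(con)
  readr::write_csv(rows, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_features()]
#'
#' @param path CSV path.
#' @return tibble.
#' @export
read_features <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Read / write stimulus metadata CSV
#'
#' Columns: `stimulus_id`, `valence`, `arousal_rating`, `arousal_level`,
#' `sf_value`, `sf_level`, `mean_luminance`.
#'
#' @param path CSV path.
#' @return tibble of stimulus metadata.
#' @export
read_stimulus_meta <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- c("stimulus_id", "valence", "arousal_rating", "arousal_level",
                "sf_value", "sf_level", "mean_luminance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("stimulus metadata CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df
}

#' @rdname read_stimulus_meta
#' @param meta tibble of stimulus metadata.
#' @export
write_stimulus_meta <- function(meta, path) {
  readr::write_csv(meta, path)
  invisible(path)
}

#' Write cross-validation metrics to JSON
#'
#' Serializes the per-fold metric sets and the fold-mean and fold-sd of
#' each metric.
#'
#' @param cv_result result of [run_cv()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(cv_result, path) {
  jsonlite::write_json(
    list(
      per_fold = cv_result$per_fold,
      summary = cv_result$summary
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
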