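#' Analysis run configuration
#'
#' Bundles every tunable the pipeline exposes, with the defaults used
#' throughout: a fixed random seed of 1004 applied to all randomized
#' stages, 360 frames per 6-s trial at 60 fps, the preprocessing
#' thresholds (10% jump start, 5% jump end, D_RATIO bounds 40/160, 30-frame
#' interpolation limit) and k = 6 for DTW clustering.
#'
#' @param random_seed integer seed used for every source of randomness.
#' @param cv_folds number of grouped cross-validation folds; 3, 5 or 7.
#' @param smote_k_neighbors SMOTE neighbor count in 1..5, or `NA` to
#'   disable oversampling.
#' @param classifier_name one of [classifier_roster()].
#' @param frames_per_trial frames per trial (default 360).
#' @param jump_start_pct percent frame-to-frame change that opens a jump
#'   artifact interval.
#' @param jump_end_pct percent change (vs. the last accepted frame) that
#'   closes it.
#' @param d_ratio_low,d_ratio_high absolute D_RATIO bounds; values outside
#'   `(low, high)` are marked missing.
#' @param max_gap_frames longest missing run that is interpolated rather
#'   than causing trial exclusion.
#' @param dtw_k number of DTW k-means clusters.
#' @return A `run_config` list.
#' @export
run_config <- function(random_seed = 1004L,
                       cv_folds = 5L,
                       smote_k_neighbors = NA_integer_,
                       classifier_name = "logistic",
                       frames_per_trial = 360L,
                       jump_start_pct = 10,
                       jump_end_pct = 5,
                       d_ratio_low = 40,
                       d_ratio_high = 160,
                       max_gap_frames = 30L,
                       dtw_k = 6L) {
  if (!cv_folds %in% c(3L, 5L, 7L)) {
    stop("`cv_folds` must be 3, 5 or 7")
  }
  if (!is.na(smote_k_neighbors) &&
      !(smote_k_neighbors %in% 1:5)) {
    stop("`smote_k_neighbors` must be in 1..5 or NA (disabled)")
  }
  if (!classifier_name %in% classifier_roster()) {
    stop("unknown classifier_name: ", classifier_name)
  }
  if (frames_per_trial < 2) stop("`frames_per_trial` must be >= 2")
  thresholds <- c(jump_start_pct, jump_end_pct, d_ratio_low, d_ratio_high,
                  max_gap_frames)
  if (any(thresholds <= 0)) stop("all thresholds must be positive")
  if (jump_end_pct > jump_start_pct) {
    stop("`jump_end_pct` must not exceed `jump_start_pct`")
  }
  if (!(d_ratio_low < 100 && 100 < d_ratio_high)) {
    stop("D_RATIO bounds must bracket the baseline value 100")
  }
  if (dtw_k < 1) stop("`dtw_k` must be >= 1")
  structure(
    list(
      random_seed = as.integer(random_seed),
      cv_folds = as.integer(cv_folds),
      smote_k_neighbors = if (is.na(smote_k_neighbors)) NA_integer_
                          else as.integer(smote_k_neighbors),
      classifier_name = classifier_name,
      frames_per_trial = as.integer(frames_per_trial),
      jump_start_pct = jump_start_pct,
      jump_end_pct = jump_end_pct,
      d_ratio_low = d_ratio_low,
      d_ratio_high = d_ratio_high,
      max_gap_frames = as.integer(max_gap_frames),
      dtw_k = as.integer(dtw_k)
    ),
    class = "run_config"
  )
}

#' Load a run configuration from a YAML file
#'
#' Keys absent from the file take the [run_config()] defaults; unknown
#' keys and out-of-range values are errors.
#'
#' @param path YAML file; an empty file yields the full default
#'   configuration.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  allowed <- names(formals(run_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, raw)
}
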