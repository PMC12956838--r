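#' Gradient-based spatial-frequency score of a grayscale image
#'
#' Captures local intensity variation as the mean absolute first
#' difference between horizontally adjacent pixels and between vertically
#' adjacent pixels, averaged over the two directions. The score is zero
#' iff the image is constant, invariant to adding a constant intensity,
#' and scales linearly with contrast.
#'
#' @param image numeric matrix of pixel intensities on the 0–255 scale,
#'   at least 2 x 2.
#' @return Non-negative scalar score (intensity units per pixel step).
#' @export
spatial_frequency <- function(image) {
  if (!is.matrix(image) || nrow(image) < 2 || ncol(image) < 2) {
    stop("`image` must be a numeric matrix of at least 2 x 2 pixels")
  }
  horiz <- abs(image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE])
  vert <- abs(image[-1, , drop = FALSE] - image[-nrow(image), , drop = FALSE])
  (mean(horiz) + mean(vert)) / 2
}

#' Shift an image to a target mean luminance
#'
#' Additive shift towards `target_mean` with clipping to [0, 255]; if
#' clipping moved the achieved mean, the shift is applied once more. This
#' matches a stimulus set normalized to a common mean luminance
#' (~127.5 on the 8-bit scale).
#'
#' @param image numeric matrix on the 0–255 scale.
#' @param target_mean desired mean pixel intensity (default 127.5).
#' @return Matrix with mean within 0.5 of `target_mean` (attainable for
#'   any non-degenerate image).
#' @export
normalize_luminance <- function(image, target_mean = 127.5) {
  if (length(image) == 0) stop("`image` must be non-empty")
  shifted <- pmin(pmax(image + (target_mean - mean(image)), 0), 255)
  if (abs(mean(shifted) - target_mean) > 0.5) {
    shifted <- pmin(pmax(shifted + (target_mean - mean(shifted)), 0), 255)
  }
  shifted
}

#' Bin a 1–7 arousal rating into low / mid / high
#'
#' Ratings 1–2 are low, 3–5 mid, 6–7 high. The extreme ends of the
#' underlying 9-point scale (8–9) are outside the stimulus design and are
#' rejected.
#'
#' @param rating integer rating(s) in 1..7.
#' @return Character vector over `{"low", "mid", "high"}`.
#' @export
assign_arousal_level <- function(rating) {
  if (any(!rating %in% 1:7)) {
    stop("arousal ratings must lie in 1..7 (8-9 are excluded by design)")
  }
  dplyr::case_when(
    rating <= 2 ~ "low",
    rating <= 5 ~ "mid",
    TRUE ~ "high"
  )
}

#' Default spatial-frequency level boundaries
#'
#' The five observed score ranges of the stimulus set: 5.40–6.95,
#' 7.19–11.06, 11.08–13.30, 13.32–17.68 and 17.93–47.82. Scores falling
#' between adjacent ranges map to the nearer range's level, and
#' out-of-range scores to the closest extreme level, so the effective
#' cut points are the midpoints of the inter-range gaps.
#'
#' @return Numeric vector of 4 ascending cut points.
#' @export
sf_level_boundaries <- function() {
  ranges <- matrix(c(
    5.40, 6.95,
    7.19, 11.06,
    11.08, 13.30,
    13.32, 17.68,
    17.93, 47.82
  ), ncol = 2, byrow = TRUE)
  (ranges[-5, 2] + ranges[-1, 1]) / 2
}

#' Assign a spatial-frequency level (1–5)
#'
#' Either against fixed boundaries (default: the stimulus-set ranges via
#' [sf_level_boundaries()]) or, in quantile mode, against equal-frequency
#' quintile boundaries computed from a supplied score collection.
#'
#' @param score numeric score(s).
#' @param boundaries 4 ascending cut points; ignored when `reference`
#'   is given.
#' @param reference optional numeric vector of scores from which
#'   equal-frequency (quintile) boundaries are computed.
#' @return Integer level(s) in 1..5, monotone in `score`.
#' @export
assign_sf_level <- function(score, boundaries = sf_level_boundaries(),
                            reference = NULL) {
  if (!is.null(reference)) {
    boundaries <- unname(quantile(reference, probs = (1:4) / 5, type = 7))
  }
  if (is.unsorted(boundaries) || length(boundaries) != 4) {
    stop("`boundaries` must be 4 ascending cut points")
  }
  findInterval(score, boundaries, left.open = TRUE) + 1L
}

#' Score a set of grayscale PNG images
#'
#' Reads 8-bit grayscale PNGs, normalizes luminance, and computes the
#' spatial-frequency score, SF level and mean luminance for each.
#'
#' @param paths character vector of PNG paths; stimulus ids default to
#'   file names without extension.
#' @param quantile_bins if TRUE, SF levels come from equal-frequency bins
#'   over this image set instead of the fixed boundaries.
#' @return tibble with `stimulus_id`, `sf_value`, `sf_level`,
#'   `mean_luminance`.
#' @export
score_images <- function(paths, quantile_bins = FALSE) {
  imgs <- lapply(paths, read_grayscale_png)
  imgs <- lapply(imgs, normalize_luminance)
  sf <- vapply(imgs, spatial_frequency, numeric(1))
  tibble::tibble(
    stimulus_id = sub("\\.png$", "", basename(paths)),
    sf_value = sf,
    sf_level = if (quantile_bins) assign_sf_level(sf, reference = sf)
               else assign_sf_level(sf),
    mean_luminance = vapply(imgs, mean, numeric(1))
  )
}

#' Read / write an 8-bit grayscale PNG as a 0–255 matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix on the 0–255 scale.
#' @export
read_grayscale_png <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1] # take first channel
  arr * 255
}

#' @rdname read_grayscale_png
#' @param image numeric matrix on the 0–255 scale.
#' @export
write_grayscale_png <- function(image, path) {
  png::writePNG(pmin(pmax(image / 255, 0), 1), path)
  invisible(path)
}
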