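#' SMOTE minority oversampling
#'
#' Balances a two-class feature matrix by synthesizing minority-class
#' samples: each synthetic point is `x + u * (x_nn - x)` for a minority
#' sample `x`, one of its `k_neighbors` nearest minority neighbors `x_nn`
#' (Euclidean distance), and `u` uniform on [0, 1]. Low `k_neighbors`
#' (1 or 2) gives more localized interpolation, appropriate when the
#' minority class is small. Deterministic given the seed. An already
#' balanced input is returned unchanged.
#'
#' Every output row carries provenance: original rows keep
#' `synthetic = FALSE` and their own index; synthetic rows record the two
#' source row indices, so leakage checks can verify that no synthetic
#' sample derives from a held-out row.
#'
#' @param features numeric matrix or data frame of predictors.
#' @param labels two-class label vector.
#' @param k_neighbors number of nearest minority neighbors (1–5);
#'   the minority class must have more than `k_neighbors` members.
#' @param seed integer seed.
#' @return List with `features` (matrix), `labels`, and `provenance`
#'   (tibble: synthetic, source_row, neighbor_row).
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5,
                             seed = 1004) {
  features <- as.matrix(features)
  classes <- unique(labels)
  if (length(classes) != 2) stop("SMOTE requires exactly two classes")
  counts <- table(labels)
  if (counts[1] == counts[2]) {
    return(list(
      features = features, labels = labels,
      provenance = tibble::tibble(
        synthetic = rep(FALSE, nrow(features)),
        source_row = seq_len(nrow(features)),
        neighbor_row = NA_integer_
      )
    ))
  }
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(labels == minority)
  n_min <- length(min_idx)
  if (n_min <= k_neighbors) {
    stop(sprintf(
      "minority class has %d samples but k_neighbors = %d; use a smaller k",
      n_min, k_neighbors
    ))
  }
  n_new <- max(counts) - n_min
  x_min <- features[min_idx, , drop = FALSE]
  dmat <- as.matrix(dist(x_min))
  diag(dmat) <- Inf
  nn <- matrix(0L, nrow = n_min, ncol = k_neighbors)
  for (i in seq_len(n_min)) {
    nn[i, ] <- order(dmat[i, ])[seq_len(k_neighbors)]
  }
  rng <- local_rng(seed, "smote")
  base_pick <- rep_len(seq_len(n_min), n_new)[sample.int(n_new)]
  nn_pick <- nn[cbind(base_pick,
                      sample.int(k_neighbors, n_new, replace = TRUE))]
  u <- runif(n_new)
  synth <- x_min[base_pick, , drop = FALSE] +
    u * (x_min[nn_pick, , drop = FALSE] - x_min[base_pick, , drop = FALSE])
  list(
    features = rbind(features, synth),
    labels = c(labels, rep(minority, n_new)),
    provenance = tibble::tibble(
      synthetic = c(rep(FALSE, nrow(features)), rep(TRUE, n_new)),
      source_row = c(seq_len(nrow(features)), min_idx[base_pick]),
      neighbor_row = c(rep(NA_integer_, nrow(features)), min_idx[nn_pick])
    )
  )
}
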