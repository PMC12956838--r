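#' Dynamic time warping distance
#'
#' Square root of the minimum accumulated squared pointwise difference
#' over all monotone warping paths with unit steps (match, insert,
#' delete), computed by dynamic programming over the full grid with no
#' warping window. Symmetric, zero on identical sequences.
#'
#' @param a,b non-empty finite numeric sequences (lengths may differ).
#' @return Non-negative scalar distance.
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("sequences must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("sequences must be finite")
  }
  dtw_distance_cpp(as.numeric(a), as.numeric(b))
}

#' Frame-wise average pupil curve per stimulus
#'
#' @param traces list of valid [pupil_trace()] objects.
#' @return Named list of numeric curves (one per stimulus, the
#'   frame-wise arithmetic mean across participants). Stimuli with zero
#'   valid traces are simply absent.
#' @export
average_curve_per_stimulus <- function(traces) {
  if (length(traces) == 0) {
    warning("no traces supplied")
    return(list())
  }
  stim <- vapply(traces, function(x) x$stimulus_id, character(1))
  out <- lapply(split(traces, stim), function(group) {
    rowMeans(vapply(group, function(x) x$d_ratio,
                    numeric(length(group[[1]]$d_ratio))))
  })
  out[order(names(out))]
}

#' DTW k-means clustering of pupil curves
#'
#' Iterative assign-update clustering under [dtw_distance()]:
#' assignments go to the nearest centroid; centroids are refined by DTW
#' barycenter averaging (capped inner iterations) with a medoid fallback
#' whenever the barycenter fails to reduce the within-cluster cost, so
#' the objective (sum of within-cluster DTW distances) never increases.
#' Initial centroids are k distinct curves chosen by a seeded draw (ties
#' broken by stimulus id order); the result is deterministic given the
#' seed. Output clusters are renumbered in ascending order of the
#' centroid mean value.
#'
#' @param curves named list of numeric curves (e.g. from
#'   [average_curve_per_stimulus()]).
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param max_iter maximum assign-update iterations.
#' @param dba_iter inner barycenter-averaging iterations per update.
#' @return List with `assignments` (named integer vector, 1..k),
#'   `centroids` (list of k curves), `cluster_mean_level` (mean centroid
#'   D_RATIO per cluster, non-decreasing), `objective` (per-iteration
#'   total cost) and `k`.
#' @export
dtw_kmeans <- function(curves, k = 6, seed = 1004, max_iter = 25,
                       dba_iter = 10) {
  n <- length(curves)
  if (n < k) stop(sprintf("need at least k = %d curves, got %d", k, n))
  curves <- curves[order(names(curves))]
  mats <- lapply(curves, as.numeric)
  rng <- local_rng(seed, "dtw_kmeans", k)
  centroids <- mats[sort(sample.int(n, k))]
  assign_cost <- function(cents) {
    d <- vapply(cents, function(ce) {
      vapply(mats, dtw_distance_cpp, numeric(1), b = ce)
    }, numeric(n))
    list(assign = max.col(-d, ties.method = "first"),
         cost = sum(d[cbind(seq_len(n), max.col(-d, ties.method = "first"))]),
         dist = d)
  }
  state <- assign_cost(centroids)
  objective <- state$cost
  for (iter in seq_len(max_iter)) {
    new_centroids <- centroids
    for (j in seq_len(k)) {
      members <- mats[state$assign == j]
      if (length(members) == 0) {
        # reseed an empty cluster with the worst-fitted curve
        worst <- which.max(
          state$dist[cbind(seq_len(n), state$assign)]
        )
        new_centroids[[j]] <- mats[[worst]]
        next
      }
      cluster_cost <- function(ce) {
        sum(vapply(members, dtw_distance_cpp, numeric(1), b = ce))
      }
      bary <- centroids[[j]]
      for (it in seq_len(dba_iter)) bary <- dba_update_cpp(bary, members)
      # candidates: previous centroid, barycenter, medoid; keep the best
      # so the update step can never increase the objective
      medoid_costs <- vapply(members, cluster_cost, numeric(1))
      candidates <- list(centroids[[j]], bary,
                         members[[which.min(medoid_costs)]])
      costs <- vapply(candidates, cluster_cost, numeric(1))
      new_centroids[[j]] <- candidates[[which.min(costs)]]
    }
    centroids <- new_centroids
    new_state <- assign_cost(centroids)
    objective <- c(objective, new_state$cost)
    converged <- identical(new_state$assign, state$assign)
    state <- new_state
    if (converged) break
  }
  # renumber ascending by centroid mean value
  means <- vapply(centroids, mean, numeric(1))
  ord <- order(means)
  relabel <- match(seq_len(k), ord)
  assignments <- relabel[state$assign]
  names(assignments) <- names(curves)
  list(
    assignments = assignments,
    centroids = centroids[ord],
    cluster_mean_level = means[ord],
    objective = objective,
    k = k
  )
}

#' Per-cluster spatial-frequency summary
#'
#' Joins cluster assignments with stimulus metadata and reports the mean
#' SF score of each cluster next to its mean pupil level, plus the
#' per-stimulus listing. Empty clusters are reported absent with a
#' warning.
#'
#' @param result a [dtw_kmeans()] result (on stimulus-averaged curves).
#' @param metadata stimulus metadata covering all clustered stimuli.
#' @return List with `summary` (tibble: cluster, n, mean_sf,
#'   mean_level), `stimuli` (per-stimulus listing) and
#'   `level_sf_rank_correlation` (Spearman correlation between cluster
#'   mean pupil level and cluster mean SF).
#' @export
cluster_sf_summary <- function(result, metadata) {
  stim <- names(result$assignments)
  missing_meta <- setdiff(stim, metadata$stimulus_id)
  if (length(missing_meta) > 0) {
    stop("metadata missing for stimuli: ",
         paste(missing_meta, collapse = ", "))
  }
  listing <- dplyr::left_join(
    tibble::tibble(stimulus_id = stim,
                   cluster = as.integer(result$assignments)),
    dplyr::select(metadata, "stimulus_id", "sf_value", "sf_level"),
    by = "stimulus_id"
  )
  summary <- dplyr::summarise(
    dplyr::group_by(listing, .data$cluster),
    n = dplyr::n(),
    mean_sf = mean(.data$sf_value),
    .groups = "drop"
  )
  summary$mean_level <- result$cluster_mean_level[summary$cluster]
  absent <- setdiff(seq_len(result$k), summary$cluster)
  if (length(absent) > 0) {
    warning("empty cluster(s): ", paste(absent, collapse = ", "))
  }
  rho <- if (nrow(summary) > 2) {
    cor(summary$mean_level, summary$mean_sf, method = "spearman")
  } else NA_real_
  list(
    summary = dplyr::arrange(summary, .data$cluster),
    stimuli = listing,
    level_sf_rank_correlation = rho
  )
}
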