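#!/usr/bin/env Rscript
# Stage 4: exploratory DTW k-means clustering of stimulus-averaged
# pupil curves (k = 6), and the spatial-frequency profile of each
# cluster. Clusters are numbered in ascending order of mean pupil size;
# the expected picture is that the most constricted cluster carries the
# highest-SF stimuli. Clustering is exploratory only: nothing here feeds
# the classification stage.

suppressPackageStartupMessages(library(pupilvalence))

clean <- readr::read_csv("results/data/clean.csv", show_col_types = FALSE)
meta <- read_stimulus_meta("results/data/stimuli.csv")

traces <- lapply(
  split(clean, paste(clean$participant_id, clean$stimulus_id, sep = "\r")),
  function(df) pupil_trace(df$participant_id[1], df$stimulus_id[1],
                           df$d_ratio)
)
curves <- average_curve_per_stimulus(traces)
message("clustering ", length(curves), " stimulus-averaged curves")

km <- dtw_kmeans(curves, k = 6, seed = 1004)
sfsum <- cluster_sf_summary(km, meta)
print(sfsum$summary)
message(sprintf(
  "Spearman correlation, cluster mean pupil level vs mean SF: %.3f",
  sfsum$level_sf_rank_correlation
))

readr::write_csv(sfsum$summary, "results/cluster_sf_summary.csv")
readr::write_csv(sfsum$stimuli, "results/cluster_assignments.csv")
centroids <- purrr::map_dfr(seq_along(km$centroids), function(j) {
  tibble::tibble(cluster = j, frame = seq_along(km$centroids[[j]]),
                 d_ratio = km$centroids[[j]])
})
readr::write_csv(centroids, "results/cluster_centroids.csv")
message("wrote cluster tables under results/")
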