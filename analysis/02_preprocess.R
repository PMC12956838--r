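#!/usr/bin/env Rscript
# Stage 2: clean the pupil traces.
#
# Applies the rule-based cleaning sequence to every trial: baseline
# normalization to D_RATIO, the 10%/5% frame-to-frame jump rule, the
# 40/160 absolute range gate, PCHIP interpolation of missing runs of up
# to 30 frames, and exclusion of trials with longer or unanchored runs.
# Writes the cleaned valid traces and a per-trial validity report.

suppressPackageStartupMessages({
  library(pupilvalence)
  library(purrr)
})

raws <- read_trials("results/data/trials.csv")
pp <- preprocess_dataset(raws, run_config())
print(pp$summary)

clean <- purrr::map_dfr(pp$valid, function(tr) {
  tibble::tibble(
    participant_id = tr$participant_id,
    stimulus_id = tr$stimulus_id,
    frame = seq_along(tr$d_ratio),
    d_ratio = tr$d_ratio
  )
})
readr::write_csv(clean, "results/data/clean.csv")

report <- purrr::map(pp$traces, function(tr) {
  list(
    participant_id = tr$participant_id,
    stimulus_id = tr$stimulus_id,
    valid = tr$valid,
    gaps = tr$gaps
  )
})
jsonlite::write_json(unname(report), "results/preprocess_report.json",
                     dataframe = "rows", auto_unbox = TRUE)
message("kept ", pp$summary$n_valid, " of ", pp$summary$n_trials,
        " trials; report in results/preprocess_report.json")
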