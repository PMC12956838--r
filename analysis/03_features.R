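#!/usr/bin/env Rscript
# Stage 3: extract the 45 waveform features per valid trial.
#
# Summary statistics, constriction/recovery latencies and ratios, the
# area under the pupil curve (total and per 60-frame interval) and the
# frame-to-frame change sums, plus their start-normalized variants.
# Trials whose extraction fails (zero variance) are dropped and logged.

suppressPackageStartupMessages(library(pupilvalence))

clean <- readr::read_csv("results/data/clean.csv", show_col_types = FALSE)
meta <- read_stimulus_meta("results/data/stimuli.csv")

traces <- lapply(
  split(clean, paste(clean$participant_id, clean$stimulus_id, sep = "\r")),
  function(df) pupil_trace(df$participant_id[1], df$stimulus_id[1],
                           df$d_ratio)
)
tab <- extract_feature_table(traces, meta)
excl <- attr(tab, "exclusions")
message("feature rows: ", nrow(tab), "; exclusions: ", nrow(excl))
if (nrow(excl) > 0) print(excl)

write_features(tab, "results/features.csv")
message("wrote results/features.csv (", nrow(tab), " x ",
        length(feature_names()), " features + metadata)")
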