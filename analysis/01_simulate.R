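#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Emulates the study design the pipeline assumes: 40 participants
# passively viewing 50 grayscale stimuli (25 positive / 25 negative),
# monocular pupil diameter at 60 fps for 6 s (360 frames) per trial,
# normalized to an individual baseline of 100. Blink dropouts and
# single-frame spikes are injected so the cleaning stage has real work
# to do. Also writes a few sinusoidal grating PNGs as fixtures for the
# spatial-frequency measure.

suppressPackageStartupMessages(library(pupilvalence))

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- generator_config(seed = 1004L)
ds <- generate_dataset(cfg)
message("generated ", length(ds$trials), " trials (",
        cfg$n_participants, " participants x ",
        cfg$n_positive + cfg$n_negative, " stimuli)")

write_trials(ds$trials, file.path(out_dir, "trials.csv"))
write_stimulus_meta(ds$metadata, file.path(out_dir, "stimuli.csv"))

grating_dir <- file.path(out_dir, "gratings")
dir.create(grating_dir, showWarnings = FALSE)
for (cyc in c(2, 4, 8, 16, 32)) {
  write_grayscale_png(
    generate_grating_image(cyc, size_px = 128),
    file.path(grating_dir, sprintf("grating_%02dcyc.png", cyc))
  )
}
message("wrote trials.csv, stimuli.csv and 5 grating fixtures under ",
        out_dir)
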