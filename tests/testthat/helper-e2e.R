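# one full default-scale synthetic run, computed once and shared by the
# end-to-end tests (40 participants x 50 stimuli, seed 1004)
.e2e_cache <- new.env(parent = emptyenv())

default_e2e_run <- function() {
  if (!exists("run", envir = .e2e_cache)) {
    cfg <- generator_config()
    ds <- generate_dataset(cfg)
    pp <- preprocess_dataset(ds$trials)
    tab <- extract_feature_table(pp$valid, ds$metadata)
    assign("run", list(config = cfg, dataset = ds, preprocessed = pp,
                       features = tab),
           envir = .e2e_cache)
  }
  get("run", envir = .e2e_cache)
}
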