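test_that("stimulus set matches the design counts and is reproducible", {
  meta <- generate_stimulus_set(generator_config())
  expect_equal(sum(meta$valence == "positive"), 25)
  expect_equal(sum(meta$valence == "negative"), 25)
  expect_true(all(meta$arousal_rating %in% 1:7))
  expect_true(all(sort(unique(meta$sf_level)) == 1:5))
  expect_true(all(abs(meta$mean_luminance - 127.5) < 1))
  # arousal level consistent with the rating thresholds
  expect_equal(meta$arousal_level, assign_arousal_level(meta$arousal_rating))
  expect_identical(meta, generate_stimulus_set(generator_config()))

  tiny <- generate_stimulus_set(generator_config(n_positive = 1L,
                                                 n_negative = 1L))
  expect_equal(nrow(tiny), 2)
  expect_true(all(tiny$sf_level %in% 1:5))
})

test_that("clean waveform template obeys its closed form", {
  flat <- generate_clean_trace(waveform_params(0, 50, 100, 100), 360)
  expect_equal(flat, rep(100, 360))

  p <- waveform_params(20, 50, 100, 105)
  d <- generate_clean_trace(p, 360)
  expect_equal(d[1], 100)
  expect_equal(min(d), 80)
  expect_equal(which.min(d), 50)
  # closed-form finish: P_end - (P_end - (100 - C)) * exp(-310 / tau)
  expect_equal(d[360], 105 - 25 * exp(-310 / 100), tolerance = 1e-12)
  # doubling C doubles the constriction depth
  d2 <- generate_clean_trace(waveform_params(40, 50, 100, 105), 360)
  expect_equal(100 - min(d2), 2 * (100 - min(d)), tolerance = 1e-9)

  expect_error(waveform_params(-1, 50, 100, 100), "C must be")
  expect_error(waveform_params(20, 50, 100, 70), "P_end")
})

test_that("trial sampling is deterministic and null under zero effect", {
  cfg <- small_gen_config(valence_effect_size = 0,
                          noise_sd_by_valence = c(positive = 0, negative = 0),
                          noise_sd_jitter = 0,
                          trial_sd = c(depth = 0, plateau = 0, tmin = 0))
  meta <- generate_stimulus_set(cfg)
  pos <- meta[meta$valence == "positive", ][1, ]
  neg <- pos
  neg$valence <- "negative"
  a <- sample_trial(pos, "p1", cfg)
  b <- sample_trial(neg, "p1", cfg)
  # same SF/arousal, zero effect, zero noise -> identical traces
  expect_equal(a$values, b$values, tolerance = 1e-12)

  cfg2 <- small_gen_config()
  m <- generate_stimulus_set(cfg2)[1, ]
  expect_identical(sample_trial(m, "p1", cfg2)$values,
                   sample_trial(m, "p1", cfg2)$values)
})

test_that("positive valence yields larger population AUPC", {
  cfg <- generator_config(n_participants = 6L, blink_rate = 0,
                          spike_rate = 0)
  ds <- generate_dataset(cfg) # 6 x 50 = 300 trials, 150 per class
  pp <- preprocess_dataset(ds$trials)
  tab <- extract_feature_table(pp$valid, ds$metadata)
  mean_pos <- mean(tab$aupc[tab$valence == "positive"])
  mean_neg <- mean(tab$aupc[tab$valence == "negative"])
  expect_gt(mean_pos, mean_neg)
})

test_that("class separation in AUPC grows with the effect size", {
  sep <- vapply(c(0, 0.5, 1), function(es) {
    cfg <- generator_config(n_participants = 5L, blink_rate = 0,
                            spike_rate = 0, valence_effect_size = es)
    ds <- generate_dataset(cfg) # 250 trials, 125 per class
    pp <- preprocess_dataset(ds$trials)
    tab <- extract_feature_table(pp$valid, ds$metadata)
    mean(tab$aupc[tab$valence == "positive"]) -
      mean(tab$aupc[tab$valence == "negative"])
  }, numeric(1))
  expect_true(all(diff(sep) > 0))
  expect_lt(abs(sep[1]), abs(sep[3])) # null separation is the smallest
})

test_that("higher spatial frequency suppresses the sustained response", {
  cfg <- small_gen_config(valence_effect_size = 0, noise_sd_jitter = 0,
                          noise_sd_by_valence = c(positive = 0.5,
                                                  negative = 0.5))
  meta <- generate_stimulus_set(cfg)
  sustained <- vapply(seq_len(nrow(meta)), function(i) {
    m <- meta[i, ]
    mean(vapply(sprintf("q%02d", 1:8), function(p) {
      tr <- sample_trial(m, p, cfg)
      mean(100 * tr$values[51:360] / tr$baseline)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(meta$sf_value, sustained, method = "spearman"), -0.5)
})

test_that("artifact injection respects rates and the exclusion boundary", {
  cfg <- small_gen_config()
  meta <- generate_stimulus_set(cfg)
  clean <- sample_trial(meta[1, ], "p1", cfg)
  quiet <- generator_config(blink_rate = 0, spike_rate = 0)
  expect_identical(inject_artifacts(clean, quiet, 1)$values, clean$values)

  # a 31-frame dropout excludes the trial; a 10-frame one is interpolated
  drop31 <- clean
  drop31$values[100:130] <- clean$baseline * 0.2
  expect_false(preprocess_trial(drop31)$valid)
  drop10 <- clean
  drop10$values[100:109] <- clean$baseline * 0.2
  expect_true(preprocess_trial(drop10)$valid)
})

test_that("expected injected-missing fraction tracks the blink budget", {
  cfg <- generator_config(n_participants = 2L, spike_rate = 0,
                          blink_rate = 1.5,
                          blink_duration_range = c(10L, 20L))
  ds <- generate_dataset(cfg) # 100 trials
  frac <- mean(vapply(ds$trials, function(tr) {
    mean(100 * tr$values / tr$baseline < 40)
  }, numeric(1)))
  expected <- 1.5 * 15 / 360 # rate x mean duration / frames
  # blink overlap makes the realized fraction slightly smaller
  expect_lt(abs(frac - expected) / expected, 0.2)
})

test_that("dataset generation is fully reproducible and sized correctly", {
  cfg <- generator_config(n_participants = 2L, n_positive = 2L,
                          n_negative = 2L)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_length(ds1$trials, 8)
  expect_identical(ds1$metadata, ds2$metadata)
  expect_identical(
    lapply(ds1$trials, function(x) x$values),
    lapply(ds2$trials, function(x) x$values)
  )
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(ds1$trials, p1)
  write_trials(ds2$trials, p2)
  expect_identical(readLines(p1), readLines(p2)) # byte-identical output
})

test_that("grating fixtures have the stated mean, contrast and SF order", {
  flat <- generate_grating_image(0, 32)
  expect_equal(sd(as.numeric(flat)), 0)
  g2 <- generate_grating_image(2, 64)
  g4 <- generate_grating_image(4, 64)
  expect_equal(mean(g2), 127.5, tolerance = 0.5)
  expect_gt(spatial_frequency(g4), spatial_frequency(g2))
  expect_equal(spatial_frequency(generate_grating_image(4, 64, 0)), 0)
})
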