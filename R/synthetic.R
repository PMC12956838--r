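#' Configuration of the synthetic pupillometry dataset generator
#'
#' Defaults emulate the study conditions the pipeline assumes: 40
#' participants, 50 grayscale stimuli (25 positive / 25 negative), 6-s
#' trials of 360 frames at 60 fps, a constriction-then-recovery waveform
#' whose depth, minimum latency, recovery plateau and variability differ
#' by valence, a sustained-constriction effect of stimulus spatial
#' frequency, arousal-dependent response amplitude, AR(1) Gaussian
#' measurement noise, and blink/spike artifacts that exercise the
#' cleaning rules.
#'
#' Valence effects are parameterized as per-valence pairs; the
#' `valence_effect_size` multiplier scales each pair's deviation from its
#' midpoint, so 0 removes the class signal entirely and 1 gives the
#' default (separable) effect.
#'
#' @param n_participants,n_positive,n_negative design counts.
#' @param frames_per_trial frames per trial (default 360).
#' @param constriction_depth_by_valence named pair (positive, negative) of
#'   constriction depths C in D_RATIO units; negative is deeper.
#' @param drop_latency_by_valence named pair of times-to-minimum t_min in
#'   frames; negative constricts faster.
#' @param recovery_plateau_by_valence named pair of asymptotic recovery
#'   levels P_end in D_RATIO units; negative recovers less.
#' @param noise_sd_by_valence named pair of AR(1) innovation standard
#'   deviations; negative traces fluctuate more.
#' @param noise_sd_jitter log-normal sigma of the per-trial multiplier on
#'   the innovation standard deviation, so trace-roughness features carry
#'   class signal without being deterministic class markers.
#' @param recovery_rate exponential recovery time constant tau (frames).
#' @param valence_effect_size multiplier >= 0 scaling all four valence
#'   contrasts about their midpoints.
#' @param sf_constriction_gain D_RATIO units of extra constriction depth
#'   and plateau suppression per standardized SF unit.
#' @param arousal_amplitude_gain multiplicative amplitude gain per arousal
#'   level step (low = 1, mid = gain, high = gain^2).
#' @param participant_sd named vector (`depth`, `plateau`, `tmin`) of
#'   between-participant random-effect standard deviations.
#' @param trial_sd named vector (`depth`, `plateau`, `tmin`) of
#'   trial-to-trial jitter standard deviations.
#' @param ar_coefficient AR(1) coefficient of the measurement noise.
#' @param blink_rate expected blink dropouts per trial (Poisson).
#' @param blink_duration_range inclusive frame range of blink durations;
#'   durations above 30 frames trigger downstream trial exclusion.
#' @param spike_rate expected single-frame spikes per trial (Poisson).
#' @param baseline_mean,baseline_sd distribution of the per-participant
#'   raw baseline diameter (arbitrary device units).
#' @param seed integer seed; the generator is fully deterministic given
#'   the config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_participants = 40L,
                             n_positive = 25L,
                             n_negative = 25L,
                             frames_per_trial = 360L,
                             constriction_depth_by_valence =
                               c(positive = 16.5, negative = 21.5),
                             drop_latency_by_valence =
                               c(positive = 54, negative = 46),
                             recovery_plateau_by_valence =
                               c(positive = 103.5, negative = 98.5),
                             noise_sd_by_valence =
                               c(positive = 1.45, negative = 1.95),
                             noise_sd_jitter = 0.25,
                             recovery_rate = 80,
                             valence_effect_size = 1,
                             sf_constriction_gain = 4,
                             arousal_amplitude_gain = 1.15,
                             participant_sd =
                               c(depth = 3.5, plateau = 3.0, tmin = 5),
                             trial_sd =
                               c(depth = 3.0, plateau = 2.5, tmin = 5),
                             ar_coefficient = 0.8,
                             blink_rate = 0.7,
                             blink_duration_range = c(4L, 36L),
                             spike_rate = 0.8,
                             baseline_mean = 4.0,
                             baseline_sd = 0.5,
                             seed = 1004L) {
  stopifnot(
    n_participants >= 1, n_positive >= 0, n_negative >= 0,
    n_positive + n_negative >= 2,
    frames_per_trial %% 6 == 0, frames_per_trial >= 12,
    valence_effect_size >= 0,
    all(noise_sd_by_valence >= 0),
    ar_coefficient >= 0, ar_coefficient < 1,
    blink_rate >= 0, spike_rate >= 0,
    blink_duration_range[1] >= 1,
    blink_duration_range[2] >= blink_duration_range[1],
    baseline_mean > 0
  )
  structure(as.list(environment()), class = "generator_config")
}

#' Waveform template parameters for one trial
#'
#' The deterministic trial template starts at 100, falls smoothly
#' (half-cosine) to its minimum `100 - C` at frame `t_min`, then relaxes
#' exponentially with time constant `tau` towards the plateau `P_end`.
#'
#' @param C constriction depth in D_RATIO units (>= 0).
#' @param t_min 1-based frame of the minimum.
#' @param tau exponential recovery time constant in frames (> 0).
#' @param P_end asymptotic recovery level; must satisfy
#'   `P_end >= 100 - C`.
#' @return A `waveform_params` list.
#' @export
waveform_params <- function(C, t_min, tau, P_end) {
  if (C < 0) stop("constriction depth C must be >= 0")
  if (t_min < 1) stop("t_min must be >= 1")
  if (tau <= 0) stop("tau must be > 0")
  if (P_end < 100 - C) stop("P_end must be >= 100 - C")
  structure(list(C = C, t_min = t_min, tau = tau, P_end = P_end),
            class = "waveform_params")
}

#' Evaluate the noiseless constriction-then-recovery template
#'
#' @param params a [waveform_params()].
#' @param frames number of frames.
#' @return Numeric D_RATIO vector: exactly 100 at frame 1, exactly
#'   `100 - C` at frame `t_min`, approaching `P_end` thereafter.
#' @export
generate_clean_trace <- function(params, frames = 360) {
  if (!inherits(params, "waveform_params")) {
    stop("`params` must be a waveform_params object")
  }
  if (params$t_min > frames) stop("t_min exceeds the trial length")
  t <- seq_len(frames)
  out <- numeric(frames)
  if (params$t_min == 1) {
    out[1] <- 100 - params$C
  } else {
    fall <- t <= params$t_min
    out[fall] <- 100 - params$C *
      (1 - cos(pi * (t[fall] - 1) / (params$t_min - 1))) / 2
  }
  rec <- t > params$t_min
  out[rec] <- params$P_end - (params$P_end - (100 - params$C)) *
    exp(-(t[rec] - params$t_min) / params$tau)
  out
}

# standardization constants for the SF effect: moments of the stimulus-set
# SF distribution the generator emulates (mean 14.27, sd 8.61)
.sf_standardize <- function(sf_value) (sf_value - 14.27) / 8.61

# resolve a per-valence parameter pair under the effect-size multiplier
.valence_param <- function(pair, valence, effect_size) {
  mid <- mean(pair)
  mid + effect_size * (pair[[valence]] - mid)
}

#' Generate the synthetic stimulus set
#'
#' Draws `n_positive + n_negative` stimuli with arousal ratings on 1–7
#' (binned low/mid/high), continuous SF scores spread over the five level
#' ranges (each level non-empty at default counts), and mean luminance
#' ~127.5. Arousal and SF are drawn independently of valence, so only the
#' pupil waveform carries class signal.
#'
#' @param config a [generator_config()].
#' @return Stimulus metadata tibble (see [read_stimulus_meta()]).
#' @export
generate_stimulus_set <- function(config = generator_config()) {
  n <- config$n_positive + config$n_negative
  rng <- local_rng(config$seed, "stimulus_set")
  valence <- c(rep("positive", config$n_positive),
               rep("negative", config$n_negative))
  # arousal ratings weighted towards the middle of the 1-7 scale
  rating <- sample(1:7, n, replace = TRUE,
                   prob = c(0.06, 0.08, 0.15, 0.20, 0.15, 0.20, 0.16))
  # cycle through the five level ranges so each is populated, drawing the
  # continuous score uniformly within the range
  ranges <- matrix(c(5.40, 6.95, 7.19, 11.06, 11.08, 13.30,
                     13.32, 17.68, 17.93, 47.82),
                   ncol = 2, byrow = TRUE)
  lvl <- rep_len(1:5, n)[sample.int(n)]
  sf_value <- ranges[lvl, 1] + runif(n) * (ranges[lvl, 2] - ranges[lvl, 1])
  tibble::tibble(
    stimulus_id = sprintf("stim%03d", seq_len(n)),
    valence = valence,
    arousal_rating = as.integer(rating),
    arousal_level = assign_arousal_level(rating),
    sf_value = sf_value,
    sf_level = assign_sf_level(sf_value),
    mean_luminance = 127.5 + rnorm(n, 0, 0.07)
  )
}

#' Simulate one raw pupil trial
#'
#' Composes the waveform template with valence, spatial-frequency and
#' arousal effects, participant and trial random effects, AR(1) Gaussian
#' noise, and rescales by the participant's raw baseline diameter.
#' Deterministic given (`meta`, `participant_id`, `config`, `seed`).
#'
#' @param meta one-row stimulus metadata (as from
#'   [generate_stimulus_set()]).
#' @param participant_id participant identifier (also seeds the
#'   participant's random effects).
#' @param config a [generator_config()].
#' @param seed integer seed for the trial-level randomness.
#' @return A [raw_pupil_trace()] without artifacts.
#' @export
sample_trial <- function(meta, participant_id, config = generator_config(),
                         seed = config$seed) {
  es <- config$valence_effect_size
  v <- meta$valence
  C <- .valence_param(config$constriction_depth_by_valence, v, es)
  t_min <- .valence_param(config$drop_latency_by_valence, v, es)
  P_end <- .valence_param(config$recovery_plateau_by_valence, v, es)
  noise_sd <- .valence_param(config$noise_sd_by_valence, v, es)
  pe <- participant_effects(participant_id, config)
  rng <- local_rng(seed, "trial", participant_id, meta$stimulus_id)
  C <- C + pe$depth + rnorm(1, 0, config$trial_sd[["depth"]])
  P_end <- P_end + pe$plateau + rnorm(1, 0, config$trial_sd[["plateau"]])
  t_min <- t_min + pe$tmin + rnorm(1, 0, config$trial_sd[["tmin"]])
  # sustained spatial-frequency effect: high-SF stimuli constrict deeper
  # and recover to a lower plateau
  z_sf <- .sf_standardize(meta$sf_value)
  C <- C + config$sf_constriction_gain * z_sf
  P_end <- P_end - config$sf_constriction_gain * z_sf
  C <- max(C, 0)
  t_min <- min(max(round(t_min), 2), config$frames_per_trial - 1)
  P_end <- max(P_end, 100 - C)
  template <- generate_clean_trace(
    waveform_params(C, t_min, config$recovery_rate, P_end),
    config$frames_per_trial
  )
  # arousal scales the deviation from baseline (low = 1x, mid, high)
  level_idx <- match(meta$arousal_level, c("low", "mid", "high"))
  amp <- config$arousal_amplitude_gain^(level_idx - 1)
  d <- 100 + amp * (template - 100)
  # AR(1) measurement noise, stationary start
  n <- config$frames_per_trial
  phi <- config$ar_coefficient
  noise_sd <- noise_sd * exp(rnorm(1, 0, config$noise_sd_jitter))
  innov <- rnorm(n, 0, noise_sd)
  noise <- numeric(n)
  noise[1] <- innov[1] / sqrt(1 - phi^2)
  for (t in 2:n) noise[t] <- phi * noise[t - 1] + innov[t]
  raw_pupil_trace(participant_id, meta$stimulus_id,
                  (d + noise) * pe$baseline / 100, pe$baseline)
}

# per-participant random effects, deterministic in (participant_id, seed)
participant_effects <- function(participant_id, config) {
  rng <- local_rng(config$seed, "participant", participant_id)
  list(
    depth = rnorm(1, 0, config$participant_sd[["depth"]]),
    plateau = rnorm(1, 0, config$participant_sd[["plateau"]]),
    tmin = rnorm(1, 0, config$participant_sd[["tmin"]]),
    baseline = max(rnorm(1, config$baseline_mean, config$baseline_sd),
                   config$baseline_mean / 4)
  )
}

#' Inject blink dropouts and single-frame spikes into a raw trace
#'
#' Blink dropouts are runs (Poisson count with mean `blink_rate`,
#' durations uniform over `blink_duration_range`) during which the raw
#' value collapses to 10–30% of baseline, falling below the D_RATIO = 40
#' gate after normalization. Spikes are single frames inflated by 15–30%,
#' exceeding the 10% frame-to-frame jump rule. Deterministic given the
#' seed; with both rates zero the trace is returned unchanged.
#'
#' @param trace a [raw_pupil_trace()].
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return The trace with artifacts injected.
#' @export
inject_artifacts <- function(trace, config = generator_config(),
                             seed = config$seed) {
  if (config$blink_rate == 0 && config$spike_rate == 0) return(trace)
  rng <- local_rng(seed, "artifacts", trace$participant_id,
                   trace$stimulus_id)
  n <- length(trace$values)
  n_blinks <- rpois(1, config$blink_rate)
  margin <- 5L # keep artifacts off the trace boundary
  if (n_blinks > 0) {
    for (b in seq_len(n_blinks)) {
      dur <- sample(seq(config$blink_duration_range[1],
                        config$blink_duration_range[2]), 1)
      if (n - dur - 2 * margin <= 0) next
      start <- margin + sample.int(n - dur - 2 * margin, 1)
      depth <- runif(1, 0.10, 0.30)
      trace$values[start:(start + dur - 1)] <-
        trace$baseline * depth * (1 + rnorm(dur, 0, 0.05))
    }
  }
  n_spikes <- rpois(1, config$spike_rate)
  if (n_spikes > 0) {
    at <- margin + sample.int(n - 2 * margin, min(n_spikes, n - 2 * margin))
    trace$values[at] <- trace$values[at] * runif(length(at), 1.15, 1.30)
  }
  trace
}

#' Generate a horizontal sinusoidal grating image
#'
#' A standard test pattern for the spatial-frequency score: intensity
#' varies sinusoidally along x with `cycles_per_image` full cycles, mean
#' 127.5 and amplitude `contrast * 127.5`.
#'
#' @param cycles_per_image number of full cycles across the image width.
#' @param size_px image side length in pixels (>= 8).
#' @param contrast Michelson contrast in [0, 1].
#' @return `size_px` x `size_px` matrix on the 0–255 scale.
#' @export
generate_grating_image <- function(cycles_per_image, size_px = 64,
                                   contrast = 1) {
  if (cycles_per_image < 0) stop("`cycles_per_image` must be >= 0")
  if (size_px < 8) stop("`size_px` must be >= 8")
  x <- seq_len(size_px) - 1
  row <- 127.5 + contrast * 127.5 * sin(2 * pi * cycles_per_image * x / size_px)
  matrix(rep(row, each = size_px), nrow = size_px)
}

#' Generate the full synthetic dataset
#'
#' All participants x all stimuli, with artifacts injected per trial.
#' Fully reproducible from the config (which carries the seed).
#'
#' @param config a [generator_config()].
#' @return List with `trials` (list of [raw_pupil_trace()]) and
#'   `metadata` (stimulus tibble).
#' @export
generate_dataset <- function(config = generator_config()) {
  metadata <- generate_stimulus_set(config)
  participants <- sprintf("p%02d", seq_len(config$n_participants))
  trials <- vector("list", config$n_participants * nrow(metadata))
  idx <- 1L
  for (p in participants) {
    for (s in seq_len(nrow(metadata))) {
      tr <- sample_trial(metadata[s, ], p, config, config$seed)
      trials[[idx]] <- inject_artifacts(tr, config, config$seed)
      idx <- idx + 1L
    }
  }
  names(trials) <- vapply(
    trials, function(x) paste(x$participant_id, x$stimulus_id), character(1)
  )
  list(trials = trials, metadata = metadata)
}

# Seed the RNG deterministically from an integer seed plus string context,
# restoring the caller's RNG state on exit. The context is hashed onto
# 31 bits so distinct (participant, stimulus, stage) combinations get
# distinct, reproducible streams.
local_rng <- function(seed, ...) {
  ctx <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(ctx)) h <- (h * 131 + ch) %% 2147483647
  env <- parent.frame()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  withr::defer(
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    },
    envir = env
  )
  set.seed(as.integer(h))
  invisible(h)
}
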