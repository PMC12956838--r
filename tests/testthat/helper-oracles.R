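# Independent oracles used across the suite. Deliberately written in a
# plain, loop-heavy style, not sharing code paths with the package.

# Exhaustive DTW: enumerate every monotone warping path (match / insert /
# delete unit steps) recursively and take the minimum accumulated squared
# difference. Exponential; only for sequences of length <= 8.
bf_dtw <- function(a, b) {
  n <- length(a)
  m <- length(b)
  rec <- function(i, j) {
    cost <- (a[i] - b[j])^2
    if (i == n && j == m) return(cost)
    nxt <- Inf
    if (i < n && j < m) nxt <- min(nxt, rec(i + 1, j + 1))
    if (i < n) nxt <- min(nxt, rec(i + 1, j))
    if (j < m) nxt <- min(nxt, rec(i, j + 1))
    cost + nxt
  }
  sqrt(rec(1, 1))
}

# Straightforward re-implementation of the 45 features, one at a time.
ref_features <- function(d) {
  n <- length(d)
  out <- list()
  out$max <- max(d)
  out$min <- min(d)
  out$mean <- sum(d) / n
  out$std <- sqrt(sum((d - out$mean)^2) / n)
  out$start <- d[1]
  out$finish <- d[n]
  post <- d[51:n]
  out$peak <- max(post)
  out$peak_ratio <- out$peak / out$min
  out$peak_latency <- 50 + min(which(post == out$peak))
  out$drop_latency <- min(which(d == out$min))
  out$drop_ratio <- out$min / out$start
  out$recovery_ratio <- out$finish / out$start
  out$response_duration <- out$peak_latency - out$drop_latency
  out$reaction_extent <- out$drop_ratio + out$recovery_ratio
  out$stability <- out$mean / out$std
  out$range <- out$max - out$min
  out$baseline_deviation <- out$start - out$mean
  out$aupc <- sum(d)
  ds <- d * 100 / d[1]
  out$s_aupc <- sum(ds)
  L <- n / 6
  for (i in 1:6) {
    idx <- ((i - 1) * L + 1):(i * L)
    out[[paste0("aupc", i)]] <- sum(d[idx])
    out[[paste0("s_aupc", i)]] <- sum(ds[idx])
  }
  cs <- 0
  scs <- 0
  ci <- rep(0, 6)
  sci <- rep(0, 6)
  for (t in 2:n) {
    step <- abs(d[t] - d[t - 1])
    sstep <- abs(ds[t] - ds[t - 1])
    cs <- cs + step
    scs <- scs + sstep
    interval <- ceiling(t / L) # difference t vs t-1 belongs to t's interval
    ci[interval] <- ci[interval] + step
    sci[interval] <- sci[interval] + sstep
  }
  out$change_sum <- cs
  out$s_change_sum <- scs
  for (i in 1:6) {
    out[[paste0("change_sum", i)]] <- ci[i]
    out[[paste0("s_change_sum", i)]] <- sci[i]
  }
  unlist(out)[feature_names()]
}

# the piecewise-linear worked trace: 100 -> 80 over frames 1-60, flat 80
# to frame 300, then 80 -> 90 over frames 301-360
piecewise_trace <- function() {
  d <- c(
    100 - 20 * (0:59) / 59,
    rep(80, 240),
    80 + 10 * (1:60) / 60
  )
  pupil_trace("p1", "s1", d)
}

# a small configuration for fast Monte-Carlo generator tests
small_gen_config <- function(...) {
  generator_config(
    n_participants = 4L, n_positive = 6L, n_negative = 6L,
    blink_rate = 0, spike_rate = 0, ...
  )
}

make_trace <- function(d, participant = "p1", stimulus = "s1") {
  pupil_trace(participant, stimulus, d)
}
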