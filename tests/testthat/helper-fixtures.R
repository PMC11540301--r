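# Fixture builders and independent oracles used across test files.

# tiny hand-built session: deterministic laps of constant running
make_test_session <- function(n = 100, n_rois = 2, track = 200, fs = 30,
                              rewards = integer(), teleports = integer(),
                              env = data.frame(env_label = "familiar",
                                               start_frame = 0L),
                              seed = 1) {
  set.seed(seed)
  pos <- seq(0, track, length.out = n)
  rois <- lapply(seq_len(n_rois), function(i)
    roi_trace(sprintf("roi%02d", i), if (i == n_rois && n_rois > 1) "bleb" else "axon",
              100 + rnorm(n)))
  session(session_id = "test", source = "LC", frame_rate_hz = fs,
          track_length_cm = track, env_schedule = env,
          behavior = behavior_raw(pos, rewards, teleports), rois = rois,
          meta = list(mouse = "m1"))
}

# quick simulator config for tests (short sessions, few ROIs)
quick_cfg <- function(...) {
  defaults <- list(n_sessions = 1, axons_per_session = 3, blebs_per_session = 3,
                   familiar_duration_s = 120, novel_duration_s = 120, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# ---- independent oracles ------------------------------------------------

# brute-force rolling percentile (same definition as compute_dff's baseline)
oracle_rolling_quantile <- function(x, window, prob) {
  n <- length(x)
  half <- window %/% 2L
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    unname(quantile(x[lo:hi], prob, type = 7))
  }, numeric(1))
}

# brute-force per-frame motion-onset detector
oracle_onsets <- function(v, fs, thr = 5, pre_s = 1.5, post_s = 3) {
  n_pre <- ceiling(pre_s * fs); n_post <- ceiling(post_s * fs)
  n <- length(v)
  out <- integer()
  for (t in seq_len(n)) {
    if (t - n_pre < 1L || t + n_post - 1L > n) next
    if (v[t] >= thr && all(v[(t - n_pre):(t - 1L)] < thr) &&
        all(v[t:(t + n_post - 1L)] >= thr))
      out <- c(out, t - 1L)
  }
  out
}

# brute-force per-(lap, bin) accumulation for covariate binning
oracle_bin <- function(values, cov, lap_index, laps, edges) {
  nb <- length(edges) - 1L
  m <- matrix(NaN, length(laps), nb)
  for (li in seq_along(laps)) {
    for (b in seq_len(nb)) {
      closed_right <- b == nb
      sel <- lap_index == laps[li] & !is.na(cov) & cov >= edges[b] &
        (if (closed_right) cov <= edges[b + 1L] else cov < edges[b + 1L])
      if (any(sel)) m[li, b] <- mean(values[sel])
    }
  }
  m
}

# random toy session for binning/onset property tests: piecewise behaviour
random_toy_behavior <- function(n = 300, fs = 30, track = 100, seed = 1) {
  set.seed(seed)
  v_true <- abs(rnorm(n, 15, 8))           # cm/s, crosses 5 often
  v_true[runif(n) < 0.3] <- 0
  pos <- numeric(n); teleports <- integer()
  p <- 0
  for (i in seq_len(n)) {
    p <- p + v_true[i] / fs
    if (p >= track) { p <- 0; teleports <- c(teleports, i - 1L) }
    pos[i] <- p
  }
  list(pos = pos, teleports = teleports, v = v_true, fs = fs, track = track)
}
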