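# Behavioural derivation: velocity, laps, immobility, motion onsets.

# Savitzky-Golay smoothing.  Interior frames use the classic symmetric
# convolution weights; edge frames fit the same-order polynomial to the
# first/last `window` samples and evaluate it at the frame (scipy's
# mode="interp").  Either way polynomials up to `order` are reproduced
# exactly everywhere.
savgol_smooth <- function(x, window = 7L, order = 5L) {
  n <- length(x)
  if (window > n) stopf("Savitzky-Golay window (%d) longer than trace (%d)", window, n)
  if (window %% 2L == 0L) stopf("window must be odd")
  half <- (window - 1L) %/% 2L
  A <- outer(-half:half, 0:order, `^`)
  H <- solve(crossprod(A), t(A))          # row j+1 = j-th poly coefficient
  w <- H[1L, ]                            # center-evaluation weights
  out <- numeric(n)
  if (n >= window) {
    interior <- (half + 1L):(n - half)
    out[interior] <- vapply(interior, function(i)
      sum(w * x[(i - half):(i + half)]), numeric(1))
    # edges: polynomial fit over the first/last `window` samples
    Afit <- outer(0:(window - 1L), 0:order, `^`)
    cf_lo <- solve(crossprod(Afit), crossprod(Afit, x[1:window]))
    cf_hi <- solve(crossprod(Afit), crossprod(Afit, x[(n - window + 1L):n]))
    for (i in 1:half) out[i] <- sum(cf_lo * (i - 1L)^(0:order))
    for (i in (n - half + 1L):n)
      out[i] <- sum(cf_hi * (i - (n - window + 1L))^(0:order))
  }
  out
}

#' Per-frame velocity from VR position
#'
#' Velocity is the backward difference of position times the frame rate,
#' smoothed with a Savitzky-Golay filter (7-frame window, degree-5
#' polynomial).  Transitions that span a teleport (where the position
#' resets to the track start and differencing is meaningless) are excluded
#' before smoothing: each contiguous run of valid differences is smoothed
#' independently, so teleports never leak large negative spikes into the
#' estimate.  Excluded frames (the first frame and each teleport frame)
#' carry the nearest valid value and are marked in `teleport_exclusion`.
#'
#' @param position_cm per-frame position in cm.
#' @param teleport_frames 0-based frames where position resets.
#' @param frame_rate_hz sampling rate in Hz.
#' @param window,order Savitzky-Golay parameters (defaults 7 and 5).
#' @return list with `velocity_cm_s` (finite, full length) and
#'   `teleport_exclusion` (logical mask of frames whose velocity was not
#'   measured directly).
#' @export
compute_velocity <- function(position_cm, teleport_frames = integer(),
                             frame_rate_hz = 30, window = 7L, order = 5L) {
  n <- length(position_cm)
  if (n < window) stopf("need at least %d frames, got %d", window, n)
  v_raw <- c(NA_real_, diff(position_cm) * frame_rate_hz)
  excl <- rep(FALSE, n)
  excl[1L] <- TRUE
  tf <- teleport_frames[teleport_frames >= 0L & teleport_frames < n]
  excl[tf + 1L] <- TRUE                  # diff into the teleport frame
  v_raw[excl] <- NA_real_

  v <- rep(NA_real_, n)
  runs <- rle(!excl)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    seg <- v_raw[idx]
    m <- length(seg)
    if (m >= window) {
      v[idx] <- savgol_smooth(seg, window, order)
    } else {
      # short segment: fit the highest identifiable polynomial order
      o <- min(order, m - 1L)
      if (o <= 0L) { v[idx] <- seg } else {
        A <- outer(0:(m - 1L), 0:o, `^`)
        cf <- solve(crossprod(A), crossprod(A, seg))
        v[idx] <- as.numeric(A %*% cf)
      }
    }
  }
  # fill excluded frames with the nearest valid value (next, else previous)
  if (anyNA(v)) {
    ok <- which(!is.na(v))
    if (!length(ok)) stopf("no valid velocity frames")
    for (i in which(is.na(v))) {
      nxt <- ok[ok > i]
      v[i] <- if (length(nxt)) v[nxt[1]] else v[max(ok[ok < i])]
    }
  }
  list(velocity_cm_s = v, teleport_exclusion = excl)
}

#' Segment frames into laps delimited by teleports
#'
#' Lap `k` spans `[teleport_{k-1}, teleport_k)` with lap 0 starting at frame
#' 0; the final (possibly incomplete) lap runs to the end of the session.
#' Reward-pause frames belong to the lap they end.  Empty laps produced by
#' a teleport at frame 0 or consecutive teleports are dropped with a log
#' line.
#'
#' @param n_frames total frame count.
#' @param teleport_frames sorted 0-based teleport frames.
#' @return list with `lap_index` (0-based per-frame integer), `lap_table`
#'   (data.frame lap/start_frame/end_frame/complete) where `complete` marks
#'   laps terminated by a teleport.
#' @export
segment_laps <- function(n_frames, teleport_frames = integer()) {
  tf <- sort(unique(as.integer(teleport_frames)))
  tf <- tf[tf >= 0L & tf < n_frames]
  bounds <- unique(c(0L, tf, as.integer(n_frames)))
  if (length(tf) && tf[1] == 0L)
    log_msg("behavior", "dropping empty lap at frame 0")
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  lap_index <- integer(n_frames)
  for (k in seq_along(starts))
    lap_index[(starts[k] + 1L):ends[k]] <- k - 1L
  list(lap_index = lap_index,
       lap_table = data.frame(lap = seq_along(starts) - 1L,
                              start_frame = starts, end_frame = ends,
                              complete = ends %in% tf | ends < n_frames,
                              stringsAsFactors = FALSE))
}

#' Per-lap behavioural metrics
#'
#' For each lap: the mean moving velocity (immobile frames, velocity below
#' `immobile_cm_s`, removed first) and the freezing ratio (immobile frames
#' over total frames).  A lap with no moving frames has freezing ratio 1
#' and an undefined (`NA`) mean moving velocity.
#'
#' @param velocity_cm_s per-frame velocity.
#' @param lap_index per-frame 0-based lap index from [segment_laps()].
#' @param env per-frame environment labels (optional).
#' @param immobile_cm_s immobility threshold, default 5 cm/s.
#' @return data.frame, one row per lap: `lap`, `env`, `start_frame`,
#'   `end_frame`, `n_frames`, `mean_moving_velocity_cm_s`, `freezing_ratio`.
#' @export
lap_metrics <- function(velocity_cm_s, lap_index, env = NULL,
                        immobile_cm_s = 5) {
  laps <- sort(unique(lap_index))
  rows <- lapply(laps, function(k) {
    idx <- which(lap_index == k)
    v <- velocity_cm_s[idx]
    moving <- v >= immobile_cm_s
    data.frame(
      lap = k,
      env = if (is.null(env)) NA_character_ else env[idx[1]],
      start_frame = idx[1] - 1L, end_frame = idx[length(idx)],
      n_frames = length(idx),
      mean_moving_velocity_cm_s = if (any(moving)) mean(v[moving]) else NA_real_,
      freezing_ratio = sum(!moving) / length(idx),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Detect motion-onset events
#'
#' An onset is a frame where velocity crosses above the running threshold
#' after at least `pre_s` of immobility and stays at or above it for at
#' least `post_s`.  A strict crossing is required (the preceding frame must
#' be below threshold), so a session that starts mid-run yields no event at
#' frame 0.
#'
#' @param velocity_cm_s per-frame (smoothed) velocity.
#' @param frame_rate_hz sampling rate.
#' @param threshold_cm_s running threshold, default 5 cm/s.
#' @param pre_s minimum immobility before the crossing, default 1.5 s.
#' @param post_s minimum sustained running after, default 3 s.
#' @return data.frame with `onset_frame` (0-based, sorted); zero rows if no
#'   event qualifies.
#' @export
detect_motion_onsets <- function(velocity_cm_s, frame_rate_hz = 30,
                                 threshold_cm_s = 5, pre_s = 1.5, post_s = 3) {
  n <- length(velocity_cm_s)
  n_pre <- ceiling(pre_s * frame_rate_hz)
  n_post <- ceiling(post_s * frame_rate_hz)
  run <- velocity_cm_s >= threshold_cm_s
  onsets <- integer()
  if (n >= n_pre + n_post) {
    run_cum <- cumsum(run)
    for (t in (n_pre + 1L):(n - n_post + 1L)) {
      if (!run[t] || run[t - 1L]) next
      # all of the previous n_pre frames immobile
      if (run_cum[t - 1L] - (if (t - n_pre - 1L >= 1L) run_cum[t - n_pre - 1L] else 0L) > 0L) next
      # all of the next n_post frames (incl. t) running
      if (run_cum[t + n_post - 1L] - run_cum[t - 1L] < n_post) next
      onsets <- c(onsets, t - 1L)
    }
  }
  data.frame(onset_frame = onsets)
}

#' Concatenate frames by locomotion state
#'
#' Retains frames where the animal is running (velocity strictly above
#' `threshold_cm_s`) or, for `state = "immobile"`, the complement, and
#' concatenates them preserving time order.  Returns the original frame
#' index of each retained sample so event frames can be mapped into the
#' concatenated timeline.
#'
#' @param arrays list of per-frame vectors (or a single vector) to filter.
#' @param velocity_cm_s per-frame velocity.
#' @param state `"running"` or `"immobile"`.
#' @param threshold_cm_s immobility cutoff, default 0.2 cm/s (the
#'   "good-behaviour" concatenation threshold).
#' @return list with `arrays` (filtered, same structure), `index` (0-based
#'   original frames retained, strictly increasing) and `empty` flag.
#' @export
filter_frames_by_motion <- function(arrays, velocity_cm_s,
                                    state = c("running", "immobile"),
                                    threshold_cm_s = 0.2) {
  state <- match.arg(state)
  keep <- if (state == "running") velocity_cm_s > threshold_cm_s
          else velocity_cm_s <= threshold_cm_s
  single <- !is.list(arrays)
  if (single) arrays <- list(arrays)
  out <- lapply(arrays, function(a) {
    if (is.matrix(a)) a[, keep, drop = FALSE] else a[keep]
  })
  if (single) out <- out[[1]]
  if (!any(keep)) log_msg("behavior", "filter_frames_by_motion: no frames match",
                          c(state = state))
  list(arrays = out, index = which(keep) - 1L, empty = !any(keep))
}

#' Full behavioural derivation for a session
#'
#' Convenience wrapper: velocity + exclusion mask, lap segmentation, both
#' immobility masks (below 5 cm/s and at or below 0.2 cm/s), motion onsets,
#' and per-lap metrics.
#'
#' @param s a [session()].
#' @param immobile_cm_s,stationary_cm_s the two immobility thresholds.
#' @return list of class `"axonav_behavior_derived"`.
#' @export
derive_behavior <- function(s, immobile_cm_s = 5, stationary_cm_s = 0.2) {
  cv <- compute_velocity(s$behavior$position_cm, s$behavior$teleport_frames,
                         s$frame_rate_hz)
  segs <- segment_laps(n_frames(s), s$behavior$teleport_frames)
  env <- env_labels(s)
  onsets <- detect_motion_onsets(cv$velocity_cm_s, s$frame_rate_hz,
                                 threshold_cm_s = immobile_cm_s)
  structure(list(
    velocity_cm_s = cv$velocity_cm_s,
    teleport_exclusion = cv$teleport_exclusion,
    lap_index = segs$lap_index,
    lap_table = segs$lap_table,
    env = env,
    immobile_5 = cv$velocity_cm_s < immobile_cm_s,
    stationary_02 = cv$velocity_cm_s <= stationary_cm_s,
    motion_onsets = onsets,
    lap_summary = lap_metrics(cv$velocity_cm_s, segs$lap_index, env,
                              immobile_cm_s)
  ), class = "axonav_behavior_derived")
}
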