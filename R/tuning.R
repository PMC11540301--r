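# Covariate-binned tuning curves and event-aligned activity matrices.

# Core per-lap binning: mean of `values` per (lap, bin) cell, NaN where a
# lap has no sample in a bin.  `bin` is a precomputed per-frame bin index
# (NA = excluded frame).
bin_by_lap <- function(values, bin, lap_index, laps, n_bins) {
  per_lap <- matrix(NaN, nrow = length(laps), ncol = n_bins)
  for (li in seq_along(laps)) {
    sel <- lap_index == laps[li] & !is.na(bin)
    if (!any(sel)) next
    sums <- tapply(values[sel], bin[sel], mean)
    per_lap[li, as.integer(names(sums))] <- sums
  }
  per_lap
}

finish_curve <- function(per_lap, edges, covariate, laps, extra = list()) {
  n_ok <- colSums(!is.nan(per_lap))
  mean_c <- colMeans(per_lap, na.rm = TRUE)
  mean_c[n_ok == 0L] <- NaN
  sem <- apply(per_lap, 2, function(col) {
    col <- col[!is.nan(col)]
    if (length(col) > 1L) stats::sd(col) / sqrt(length(col)) else NA_real_
  })
  structure(c(list(covariate = covariate, bin_edges = edges,
                   bin_centers = (edges[-1] + edges[-length(edges)]) / 2,
                   per_lap = per_lap, mean = mean_c, sem = sem,
                   n_laps_per_bin = n_ok, laps = laps), extra),
            class = "axonav_tuning_curve")
}

#' @export
print.axonav_tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning curve: %s> %d bins x %d laps\n", x$covariate,
              length(x$bin_centers), nrow(x$per_lap)))
  invisible(x)
}

# laps of a behaviour derivation that lie in `env` and are complete
laps_in_env <- function(bd, env) {
  lt <- bd$lap_table
  first_env <- bd$env[lt$start_frame + 1L]
  lt$lap[first_env == env & lt$complete]
}

#' Position-binned tuning curve
#'
#' The track is divided into `bin_cm` bins; for each completed lap in the
#' selected environment the mean activity per bin is computed, then
#' averaged across laps (NaN cells, from laps with no sample in a bin, are
#' skipped).  Reward-pause frames (position frozen at the track end) fall
#' in the final bin.  Bin centres are reported both in cm and normalised by
#' track length for cross-track pooling.
#'
#' @param values per-frame activity (typically quantile-normalised dF/F).
#' @param position_cm per-frame position.
#' @param bd behaviour derivation from [derive_behavior()].
#' @param env environment label to select laps from.
#' @param track_length_cm track length.
#' @param bin_cm bin width, default 5 cm.
#' @return an `axonav_tuning_curve`.
#' @export
bin_by_position <- function(values, position_cm, bd, env, track_length_cm,
                            bin_cm = 5) {
  laps <- laps_in_env(bd, env)
  if (!length(laps)) stopf("no completed laps in environment '%s'", env)
  edges <- seq(0, track_length_cm, by = bin_cm)
  bin <- findInterval(position_cm, edges, rightmost.closed = TRUE)
  bin[bin < 1L | bin > length(edges) - 1L] <- NA_integer_
  per_lap <- bin_by_lap(values, bin, bd$lap_index, laps, length(edges) - 1L)
  finish_curve(per_lap, edges, "position", laps,
               extra = list(bin_centers_norm =
                              ((edges[-1] + edges[-length(edges)]) / 2) / track_length_cm))
}

#' Velocity-binned tuning curve
#'
#' Velocity is divided into `bin_cm_s` bins over `range` (default 1-30
#' cm/s); frames outside the range are excluded.  Bins above
#' `complete_below` (default 14 cm/s, the fastest speed reached by every
#' animal) are flagged as not population-complete.
#'
#' @param values per-frame activity.
#' @param bd behaviour derivation (supplies velocity and laps).
#' @param env environment label.
#' @param bin_cm_s bin width, default 1 cm/s.
#' @param range velocity range, default `c(1, 30)`.
#' @param complete_below population-completeness cutoff in cm/s.
#' @return an `axonav_tuning_curve` with a `population_complete` flag per bin.
#' @export
bin_by_velocity <- function(values, bd, env, bin_cm_s = 1, range = c(1, 30),
                            complete_below = 14) {
  laps <- laps_in_env(bd, env)
  if (!length(laps)) stopf("no completed laps in environment '%s'", env)
  v <- bd$velocity_cm_s
  edges <- seq(range[1], range[2], by = bin_cm_s)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[v < range[1] | v > range[2]] <- NA_integer_
  sel_laps <- bd$lap_index %in% laps
  if (!any(!is.na(bin) & sel_laps)) stopf("no frames within the velocity range")
  per_lap <- bin_by_lap(values, bin, bd$lap_index, laps, length(edges) - 1L)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  finish_curve(per_lap, edges, "velocity", laps,
               extra = list(population_complete = centers <= complete_below))
}

#' Reward-proximity tuning curve
#'
#' Bins activity by virtual distance from the rewarded track end
#' (`mode = "distance"`, `track_length - position`, 5 cm bins) or by time
#' until the lap's reward (`mode = "time"`, 0.5 s bins over the final 10 s).
#'
#' @param values per-frame activity.
#' @param position_cm per-frame position.
#' @param bd behaviour derivation.
#' @param env environment label.
#' @param track_length_cm track length.
#' @param mode `"distance"` or `"time"`.
#' @param reward_frames 0-based reward frames (required for `mode="time"`).
#' @param frame_rate_hz sampling rate (required for `mode="time"`).
#' @param bin bin width (cm or s); default 5 cm or 0.5 s.
#' @param horizon_s time mode: how far before reward to look, default 10 s.
#' @return an `axonav_tuning_curve`; for time mode the covariate is time
#'   until reward (decreasing toward 0).
#' @export
bin_by_reward_proximity <- function(values, position_cm, bd, env,
                                    track_length_cm,
                                    mode = c("distance", "time"),
                                    reward_frames = NULL, frame_rate_hz = 30,
                                    bin = NULL, horizon_s = 10) {
  mode <- match.arg(mode)
  laps <- laps_in_env(bd, env)
  if (!length(laps)) stopf("no completed laps in environment '%s'", env)
  if (mode == "distance") {
    bin_cm <- bin %||% 5
    cov <- track_length_cm - position_cm
    edges <- seq(0, track_length_cm, by = bin_cm)
    b <- findInterval(cov, edges, rightmost.closed = TRUE)
    b[b < 1L | b > length(edges) - 1L] <- NA_integer_
    per_lap <- bin_by_lap(values, b, bd$lap_index, laps, length(edges) - 1L)
    finish_curve(per_lap, edges, "distance_to_reward", laps)
  } else {
    if (is.null(reward_frames)) stopf("mode='time' requires reward_frames")
    bin_s <- bin %||% 0.5
    n <- length(values)
    cov <- rep(NA_real_, n)                 # time until this lap's reward, s
    for (lk in laps) {
      idx <- which(bd$lap_index == lk)
      rw <- reward_frames[reward_frames >= idx[1] - 1L &
                            reward_frames <= idx[length(idx)] - 1L]
      if (!length(rw)) next
      r <- rw[1]
      pre <- idx[idx - 1L <= r]
      cov[pre] <- (r - (pre - 1L)) / frame_rate_hz
    }
    edges <- seq(0, horizon_s, by = bin_s)
    b <- findInterval(cov, edges, rightmost.closed = TRUE)
    b[is.na(cov) | cov > horizon_s] <- NA_integer_
    b[b < 1L] <- NA_integer_
    per_lap <- bin_by_lap(values, b, bd$lap_index, laps, length(edges) - 1L)
    finish_curve(per_lap, edges, "time_to_reward", laps)
  }
}

#' Activity aligned to motion onsets
#'
#' One row per qualifying onset event, columns spanning `window_s` around
#' the onset frame (time 0 = the crossing frame).  Events whose window
#' leaves the trace are excluded.  The regression segment used downstream
#' is the (-2, 0] s portion.
#'
#' @param values per-frame activity (quantile-normalised dF/F).
#' @param onsets data.frame from [detect_motion_onsets()].
#' @param frame_rate_hz sampling rate.
#' @param window_s `c(pre, post)` in seconds, default `c(-2, 3)`.
#' @return list of class `"axonav_aligned"` with `matrix` (event x time),
#'   `time_s`, `event_frames`, `mean`.
#' @export
align_to_motion_onset <- function(values, onsets, frame_rate_hz = 30,
                                  window_s = c(-2, 3)) {
  n <- length(values)
  pre <- round(window_s[1] * frame_rate_hz)
  post <- round(window_s[2] * frame_rate_hz)
  offs <- pre:post
  keep <- onsets$onset_frame + pre >= 0L & onsets$onset_frame + post < n
  ev <- onsets$onset_frame[keep]
  if (!length(ev)) stopf("no motion-onset event with a complete window")
  m <- t(vapply(ev, function(o) values[o + offs + 1L], numeric(length(offs))))
  structure(list(align_kind = "motion_onset", matrix = m,
                 time_s = offs / frame_rate_hz, event_frames = ev,
                 mean = colMeans(m)),
            class = "axonav_aligned")
}

#' Population activity aligned to an environment transition
#'
#' Rows are ROIs (mean-normalised traces), columns time around the
#' transition frame.  An optional retained-frame index (from
#' [filter_frames_by_motion()]) is applied before alignment: traces are
#' concatenated over retained frames and aligned at the first retained
#' frame at or after the event.  Windows extending past the available data
#' are NaN-padded and reported in `valid`.
#'
#' @param traces matrix ROI x frames of mean-normalised activity.
#' @param event_frame 0-based transition frame.
#' @param frame_rate_hz sampling rate.
#' @param window_s `c(pre, post)` seconds around the event; defaults to the
#'   full session extent.
#' @param frame_index optional 0-based retained-frame indices.
#' @return `axonav_aligned` with `matrix` (ROI x time), `time_s`,
#'   `orig_frames` (original frame of each column), `valid`,
#'   `population_mean`.
#' @export
align_to_transition <- function(traces, event_frame, frame_rate_hz = 30,
                                window_s = NULL, frame_index = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  n <- ncol(traces)
  if (event_frame < 0L || event_frame >= n)
    stopf("event_frame %d outside trace [0, %d)", event_frame, n)
  if (!is.null(frame_index)) {
    traces <- traces[, frame_index + 1L, drop = FALSE]
    ev <- which(frame_index >= event_frame)
    if (!length(ev) || ev[1] == 1L && length(frame_index) == 0L)
      stopf("frame mask leaves no post-event frames")
    if (ev[1] == 1L) stopf("frame mask leaves no pre-event frames")
    pivot <- ev[1]
    orig <- frame_index
  } else {
    pivot <- event_frame + 1L
    orig <- 0:(n - 1L)
  }
  nc <- ncol(traces)
  if (pivot > nc) stopf("frame mask leaves no post-event frames")
  if (is.null(window_s)) {
    lo <- 1L; hi <- nc
  } else {
    lo <- pivot + round(window_s[1] * frame_rate_hz)
    hi <- pivot + round(window_s[2] * frame_rate_hz)
  }
  cols <- lo:hi
  valid <- cols >= 1L & cols <= nc
  if (!any(valid & cols < pivot) && lo < pivot)
    stopf("window has no valid pre-event frames")
  m <- matrix(NaN, nrow = nrow(traces), ncol = length(cols))
  m[, valid] <- traces[, cols[valid], drop = FALSE]
  structure(list(align_kind = "env_switch", matrix = m,
                 time_s = (cols - pivot) / frame_rate_hz,
                 orig_frames = ifelse(valid, orig[pmin(pmax(cols, 1L), nc)], NA_integer_),
                 valid = valid,
                 population_mean = colMeans(m)),
            class = "axonav_aligned")
}

#' Bin an aligned matrix into 50-frame or lap bins
#'
#' Frames mode: non-overlapping `frames`-wide bin means, anchored at the
#' event (bins tile forward from time 0 and backward before it); a
#' remainder shorter than the bin width is dropped.  Lap mode: means over
#' the per-frame lap index of the original frames.
#'
#' @param aligned an `axonav_aligned` from [align_to_transition()].
#' @param mode `"frames"` or `"lap"`.
#' @param frames bin width in frames, default 50.
#' @param lap_index per-frame 0-based lap index (lap mode).
#' @return list with `matrix` (ROI x bin), `bin_label` (bin start time in
#'   frames relative to event, or lap id relative to the switch lap),
#'   `population_mean`.
#' @export
bin_aligned <- function(aligned, mode = c("frames", "lap"), frames = 50L,
                        lap_index = NULL) {
  mode <- match.arg(mode)
  m <- aligned$matrix[, aligned$valid, drop = FALSE]
  # column offsets in frames relative to event
  offs <- which(aligned$valid) - which(aligned$time_s == 0)
  if (mode == "frames") {
    bin_id <- floor(offs / frames)
    full <- table(bin_id)
    keep_ids <- as.integer(names(full)[full == frames])
    keep_ids <- sort(keep_ids)
    cols <- lapply(keep_ids, function(b) which(bin_id == b))
    bm <- vapply(cols, function(cc) rowMeans(m[, cc, drop = FALSE]),
                 numeric(nrow(m)))
    if (is.null(dim(bm))) bm <- matrix(bm, nrow = nrow(m))
    list(matrix = bm, bin_label = keep_ids * frames,
         population_mean = colMeans(bm))
  } else {
    if (is.null(lap_index)) stopf("lap mode requires lap_index")
    of <- aligned$orig_frames[aligned$valid]
    laps <- lap_index[of + 1L]
    ev_lap <- lap_index[aligned$orig_frames[which(aligned$time_s == 0)] + 1L]
    ids <- sort(unique(laps))
    bm <- vapply(ids, function(l) rowMeans(m[, laps == l, drop = FALSE]),
                 numeric(nrow(m)))
    if (is.null(dim(bm))) bm <- matrix(bm, nrow = nrow(m))
    list(matrix = bm, bin_label = ids - ev_lap,
         population_mean = colMeans(bm))
  }
}
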