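# Trace quality control: dF/F, ROI merging, PSD SNR, sustained-shift
# exclusion, normalisations.

#' Baseline-corrected dF/F
#'
#' The baseline `F0[t]` is a rolling low percentile (default 8th) of the raw
#' trace over a centred window, truncated at the edges.  Two window sizes
#' are used in practice: 300 frames for lap-by-lap analysis and a 2000-frame
#' sliding window that avoids flattening slow signals.
#'
#' @param raw_f raw fluorescence trace.
#' @param window_frames baseline window in frames (300 or 2000 typically).
#' @param percentile baseline percentile in `[0, 1]`, default 0.08.
#' @return per-frame `(F - F0)/F0`.
#' @export
compute_dff <- function(raw_f, window_frames = 2000L, percentile = 0.08) {
  n <- length(raw_f)
  if (n < window_frames)
    stopf("trace length (%d) shorter than baseline window (%d)", n, window_frames)
  f0 <- .rolling_quantile_cpp(as.numeric(raw_f), as.integer(window_frames),
                              percentile)
  bad <- which(f0 <= 0)
  if (length(bad))
    stopf("non-positive baseline at frame %d (F0 = %g); check trace units",
          bad[1] - 1L, f0[bad[1]])
  (raw_f - f0) / f0
}

#' Merge highly correlated axon ROIs
#'
#' Axon pairs whose long-window dF/F traces have Pearson r at or above
#' `r_min` are joined; connected components of that graph (single linkage)
#' merge into one ROI whose raw trace is the unweighted mean of the members
#' and whose dF/F is recomputed.  Blebs never merge.
#'
#' @param rois list of [roi_trace()] with `dff_long` computed (computed here
#'   if absent).
#' @param r_min Pearson threshold, default 0.7.
#' @param window_frames,percentile passed to [compute_dff()] when needed.
#' @return list of ROIs after merging; merged ROIs have `merged_from` set
#'   and an id of the form `merge(<id1>+<id2>...)`.
#' @export
merge_correlated_rois <- function(rois, r_min = 0.7, window_frames = 2000L,
                                  percentile = 0.08) {
  stopifnot(length(rois) >= 1L)
  for (i in seq_along(rois)) {
    if (is.null(rois[[i]]$dff_long))
      rois[[i]]$dff_long <- compute_dff(rois[[i]]$raw_f, window_frames, percentile)
  }
  axon_idx <- which(vapply(rois, function(r) r$kind == "axon", logical(1)))
  if (length(axon_idx) < 2L) return(rois)

  # union-find over the r >= r_min graph
  parent <- seq_along(axon_idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(axon_idx)) {
    for (b in seq_len(a - 1L)) {
      r <- stats::cor(rois[[axon_idx[a]]]$dff_long, rois[[axon_idx[b]]]$dff_long)
      if (!is.na(r) && r >= r_min) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  comp <- vapply(seq_along(axon_idx), find, integer(1))

  out <- list()
  for (cc in unique(comp)) {
    members <- axon_idx[comp == cc]
    if (length(members) == 1L) {
      out[[length(out) + 1L]] <- rois[[members]]
    } else {
      mem_rois <- rois[members]
      ids <- vapply(mem_rois, function(r) r$roi_id, character(1))
      raw <- rowMeans(vapply(mem_rois, function(r) r$raw_f,
                             numeric(length(mem_rois[[1]]$raw_f))))
      merged <- roi_trace(paste0("merge(", paste(ids, collapse = "+"), ")"),
                          "axon", raw, merged_from = ids)
      merged$dff_long <- compute_dff(raw, window_frames, percentile)
      out[[length(out) + 1L]] <- merged
      log_msg("trace_qc", "merged correlated ROIs", c(ids = paste(ids, collapse = "+")))
    }
  }
  c(out, rois[setdiff(seq_along(rois), axon_idx)])
}

# Welch power spectral density via averaged modified periodograms
# (Hann window, 50% overlap).  Returns freq (Hz) and power density.
welch_psd <- function(x, fs, segment_s = 60) {
  nseg <- round(segment_s * fs)
  n <- length(x)
  if (n < nseg) stopf("trace too short for one %g s PSD segment", segment_s)
  step <- nseg %/% 2L
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nseg) / (nseg + 1)))  # Hann
  U <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg))^2 / (fs * U)
    half <- sp[seq_len(nfreq)]
    half[2:(nfreq - 1L)] <- 2 * half[2:(nfreq - 1L)]
    acc <- acc + half
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, power = acc / length(starts))
}

#' Spectral signal-to-noise ratio of a trace
#'
#' SNR is the peak of the Welch power spectral density in the signal band
#' (0.5-1 Hz, where GCaMP6s transients live) divided by the mean power in
#' the noise band (1-3 Hz, above what the indicator can follow).
#'
#' @param dff dF/F trace (long window).
#' @param frame_rate_hz sampling rate.
#' @param segment_s Welch segment length in seconds (default 60, giving a
#'   frequency resolution well below 0.05 Hz at 30 Hz sampling).
#' @param signal_band,noise_band frequency bands in Hz.
#' @return scalar SNR.
#' @export
compute_snr <- function(dff, frame_rate_hz = 30, segment_s = 60,
                        signal_band = c(0.5, 1), noise_band = c(1, 3)) {
  psd <- welch_psd(dff, frame_rate_hz, segment_s)
  sig <- psd$freq >= signal_band[1] & psd$freq <= signal_band[2]
  noi <- psd$freq >= noise_band[1] & psd$freq <= noise_band[2]
  max(psd$power[sig]) / mean(psd$power[noi])
}

#' SNR pass/fail against the bleb reference distribution
#'
#' The threshold is `mean(bleb_snrs) + 1.5 * sd(bleb_snrs)` (sample sd); an
#' axon passes with SNR strictly greater than the threshold.
#'
#' @param axon_snrs,bleb_snrs numeric vectors.
#' @return list with `passed` (logical per axon) and `threshold`.
#' @export
snr_filter <- function(axon_snrs, bleb_snrs) {
  if (length(bleb_snrs) < 2L)
    stopf("need at least 2 bleb SNRs to define a threshold, got %d",
          length(bleb_snrs))
  thr <- mean(bleb_snrs) + 1.5 * stats::sd(bleb_snrs)
  list(passed = axon_snrs > thr, threshold = thr)
}

#' Detect a sustained upward shift in mean fluorescence
#'
#' Flags "unhealthy" axons whose fluorescence steps up and stays elevated.
#' A two-sided-capable (upward-armed) CUSUM on the robustly standardised
#' trace (median/MAD) proposes candidate change points (slack `k` sd,
#' decision threshold `h` sd; change frame = last CUSUM zero before the
#' alarm).  A candidate is confirmed when the centred moving-average of the
#' trace stays above the pre-change mean plus one pre-change sd for at least
#' `min_run` frames, or for at least `end_run` frames reaching the end of
#' the trace.  Unconfirmed alarms reset the statistic and scanning resumes.
#'
#' @param trace dF/F (long window) trace.
#' @param min_run minimum sustained run, default 2000 frames.
#' @param end_run minimum run when still elevated at trace end, default 500.
#' @param k,h CUSUM slack and decision threshold in sd units.
#' @param ma_window moving-average window (frames) for the sustained test.
#' @return list with `flagged`, and when flagged `change_frame` (0-based)
#'   and `run_length_frames`.
#' @export
detect_sustained_shift <- function(trace, min_run = 2000L, end_run = 500L,
                                   k = 0.5, h = 5, ma_window = 101L) {
  n <- length(trace)
  if (n <= end_run) stopf("trace length (%d) must exceed end_run (%d)", n, end_run)
  med <- stats::median(trace)
  s <- stats::mad(trace)
  if (s <= 0) s <- stats::sd(trace)
  if (s <= 0) return(list(flagged = FALSE))
  z <- (trace - med) / s

  # centred moving average with edge truncation
  half <- ma_window %/% 2L
  cs <- cumsum(c(0, trace))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  ma <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)

  confirm <- function(c0) {                # c0: 1-based candidate change frame
    if (c0 < 30L) return(NULL)             # too little pre-change data
    pre <- trace[seq_len(c0 - 1L)]
    thr <- mean(pre) + stats::sd(pre)
    post <- ma[c0:n]
    above <- post > thr
    if (!above[1]) return(NULL)
    run <- which(!above)
    len <- if (length(run)) run[1] - 1L else length(above)
    reaches_end <- len == length(above)
    if (len >= min_run || (reaches_end && len >= end_run))
      list(flagged = TRUE, change_frame = c0 - 1L, run_length_frames = len)
    else NULL
  }

  Splus <- 0
  last_zero <- 0L
  for (t in seq_len(n)) {
    Splus <- max(0, Splus + z[t] - k)
    if (Splus == 0) last_zero <- t
    if (Splus > h) {
      res <- confirm(last_zero + 1L)
      if (!is.null(res)) return(res)
      Splus <- 0
      last_zero <- t
    }
  }
  list(flagged = FALSE)
}

#' Quantile normalisation of dF/F
#'
#' `(x - q01) / (q99 - q01)` with the 1st and 99th percentiles (type-7
#' quantiles), so each ROI spans roughly `[0, 1]` without letting noisy
#' outliers set the scale.  Values outside `[0, 1]` are permitted.
#'
#' @param dff dF/F trace.
#' @param probs the two quantiles, default `c(0.01, 0.99)`.
#' @return normalised trace.
#' @export
normalize_quantile <- function(dff, probs = c(0.01, 0.99)) {
  q <- stats::quantile(dff, probs, names = FALSE, type = 7)
  if (q[2] <= q[1]) stopf("degenerate trace: q%g == q%g", probs[1] * 100, probs[2] * 100)
  (dff - q[1]) / (q[2] - q[1])
}

#' Mean normalisation of dF/F
#'
#' Divides by the trace mean so the output averages exactly 1; used for the
#' novelty-response analysis where ROIs are compared on a common scale.
#'
#' @param dff dF/F trace.
#' @return `dff / mean(dff)`.
#' @export
normalize_mean <- function(dff) {
  m <- mean(dff)
  if (m == 0) stopf("cannot mean-normalize a zero-mean trace")
  dff / m
}

#' Run the full QC chain on a session
#'
#' Computes both dF/F variants, merges correlated axons, computes SNR for
#' every ROI, applies the bleb-referenced SNR filter, runs sustained-shift
#' detection on surviving axons, and attaches normalised traces to the ROIs
#' that pass.
#'
#' @param s a [session()].
#' @param r_min merge threshold; `snr_*`, `shift_*` override QC defaults.
#' @param short_window,long_window dF/F window sizes.
#' @param percentile baseline percentile.
#' @param shift_min_run,shift_end_run sustained-shift run criteria.
#' @return list with `session` (ROIs replaced by the merged/annotated set)
#'   and `report` (data.frame, one row per post-merge ROI: snr, passed_snr,
#'   shift_flag, change_frame, included_final, merged_from) plus
#'   `snr_threshold`.
#' @export
qc_session <- function(s, r_min = 0.7, short_window = 300L, long_window = 2000L,
                       percentile = 0.08, shift_min_run = 2000L,
                       shift_end_run = 500L) {
  rois <- merge_correlated_rois(s$rois, r_min = r_min,
                                window_frames = long_window,
                                percentile = percentile)
  for (i in seq_along(rois)) {
    rois[[i]]$dff_short <- compute_dff(rois[[i]]$raw_f, short_window, percentile)
    if (is.null(rois[[i]]$dff_long))
      rois[[i]]$dff_long <- compute_dff(rois[[i]]$raw_f, long_window, percentile)
  }
  kind <- vapply(rois, function(r) r$kind, character(1))
  snr <- vapply(rois, function(r) compute_snr(r$dff_long, s$frame_rate_hz),
                numeric(1))
  if (sum(kind == "bleb") < 2L)
    stopf("session %s has %d bleb ROIs; need >= 2 for the SNR threshold",
          s$session_id, sum(kind == "bleb"))
  filt <- snr_filter(snr[kind == "axon"], snr[kind == "bleb"])
  passed <- logical(length(rois))
  passed[kind == "axon"] <- filt$passed

  shift_flag <- logical(length(rois))
  change_frame <- rep(NA_integer_, length(rois))
  run_len <- rep(NA_integer_, length(rois))
  for (i in which(kind == "axon" & passed)) {
    det <- detect_sustained_shift(rois[[i]]$dff_long, shift_min_run, shift_end_run)
    shift_flag[i] <- det$flagged
    if (det$flagged) {
      change_frame[i] <- det$change_frame
      run_len[i] <- det$run_length_frames
    }
  }
  included <- kind == "axon" & passed & !shift_flag
  for (i in which(included)) {
    rois[[i]]$norm_q <- normalize_quantile(rois[[i]]$dff_long)
    rois[[i]]$norm_mean <- normalize_mean(rois[[i]]$dff_long)
  }
  s$rois <- rois
  report <- data.frame(
    roi_id = vapply(rois, function(r) r$roi_id, character(1)),
    kind = kind, snr = snr, passed_snr = passed,
    shift_flag = shift_flag, change_frame = change_frame,
    run_length_frames = run_len, included_final = included,
    merged_from = vapply(rois, function(r)
      paste(r$merged_from, collapse = "+"), character(1)),
    stringsAsFactors = FALSE)
  list(session = s, report = report, snr_threshold = filt$threshold)
}
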