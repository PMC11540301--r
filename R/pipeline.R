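# Pipeline orchestration: simulate/load -> QC -> behaviour -> tuning ->
# inference, with deterministic text outputs and a markdown report.

# deterministic CSV writer: %.17g numbers, fixed column order, LF endings
write_csv_det <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.numeric(col)) fmt_num(col) else as.character(col)
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every analysis constant in one place so a run is fully
#' described by (config, seed).  Defaults are the published thresholds:
#' 5 cm/s immobility, 0.2 cm/s stationarity, 1.5 s pre / 3 s post motion
#' onset, Pearson 0.7 merge, bleb mean + 1.5 sd SNR cutoff, 300/2000-frame
#' dF/F windows, 5 cm position and 1 cm/s velocity bins over 1-30 cm/s,
#' 2 s pre-onset regression window, 50-frame bins, 2000/500-frame sustained
#' runs, alpha 0.05, and 1000 x 1000 shuffle/subsample replicates.
#'
#' @param sim a [sim_config()] or list of them (one cohort per entry);
#'   ignored when `input_dirs` is given.
#' @param input_dirs optional character vector of session directories to
#'   read instead of simulating.
#' @param seed root seed for every stochastic stage.
#' @param n_shuffles,n_subsample_reps shuffle-baseline replicates (reduce
#'   for quick runs).
#' @param resample_reps Monte-Carlo resampling repetitions.
#' @param alpha significance level.
#' @param immobile_cm_s,stationary_cm_s,onset_pre_s,onset_post_s,merge_r,
#'   snr_sd_mult,dff_short,dff_long,pos_bin_cm,vel_bin_cm_s,vel_range,
#'   onset_window_s,frame_bin,shift_min_run,shift_end_run analysis
#'   thresholds, defaults as printed above.
#' @return list of class `"axonav_pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dirs = NULL, seed = 1L,
                            n_shuffles = 200L, n_subsample_reps = 200L,
                            resample_reps = 1000L, alpha = 0.05,
                            immobile_cm_s = 5, stationary_cm_s = 0.2,
                            onset_pre_s = 1.5, onset_post_s = 3,
                            merge_r = 0.7, snr_sd_mult = 1.5,
                            dff_short = 300L, dff_long = 2000L,
                            pos_bin_cm = 5, vel_bin_cm_s = 1,
                            vel_range = c(1, 30), onset_window_s = c(-2, 3),
                            frame_bin = 50L, shift_min_run = 2000L,
                            shift_end_run = 500L) {
  cfg <- as.list(environment())
  if (inherits(cfg$sim, "axonav_sim_config")) cfg$sim <- list(cfg$sim)
  stopifnot(alpha > 0, alpha < 1, immobile_cm_s > 0, stationary_cm_s > 0)
  class(cfg) <- "axonav_pipeline_config"
  cfg
}

# population-level point set: each ROI contributes its across-lap bin
# means; per-ROI point set: lap x bin cells
curve_population_points <- function(curves) {
  list(x = unlist(lapply(curves, function(cv) cv$bin_centers)),
       y = unlist(lapply(curves, function(cv) cv$mean)))
}

curve_roi_points <- function(cv) {
  x <- rep(cv$bin_centers, each = nrow(cv$per_lap))
  y <- as.numeric(cv$per_lap)
  list(x = x, y = y)
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) sessions, applies QC, derives behaviour, builds
#' tuning curves and aligned matrices, fits population and per-ROI
#' regressions with classifications, runs the novelty shuffle-baseline
#' analysis (full-frame, 50-frame-binned, lap-binned, and running-only
#' variants), and the lap-wise behaviour ANOVA.  Re-running with the same
#' config reproduces every output bit-for-bit.
#'
#' @param cfg an [pipeline_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   deterministic CSV/JSON under it.
#' @return list of class `"axonav_results"` (the results bundle).
#' @export
run_pipeline <- function(cfg, out_dir = NULL) {
  stage <- "simulate"
  bundle <- list(config = cfg)
  res <- try({
    sessions <- list(); ground_truth <- NULL
    if (!is.null(cfg$input_dirs)) {
      stage <- "load"
      sessions <- lapply(cfg$input_dirs, read_session)
    } else {
      for (k in seq_along(cfg$sim)) {
        sc <- cfg$sim[[k]]
        sc$seed <- derive_seed(cfg$seed, 1000 * k)
        coh <- make_cohort(sc)
        sessions <- c(sessions, coh$sessions)
        ground_truth <- rbind(ground_truth, coh$ground_truth)
      }
    }
    bundle$ground_truth <- ground_truth

    stage <- "qc"
    qc <- lapply(sessions, qc_session, r_min = cfg$merge_r,
                 short_window = cfg$dff_short, long_window = cfg$dff_long,
                 shift_min_run = cfg$shift_min_run,
                 shift_end_run = cfg$shift_end_run)
    sessions <- lapply(qc, `[[`, "session")
    qc_report <- do.call(rbind, lapply(seq_along(qc), function(i) {
      r <- qc[[i]]$report
      r$session_id <- sessions[[i]]$session_id
      r$snr_threshold <- qc[[i]]$snr_threshold
      r
    }))
    bundle$qc_report <- qc_report

    stage <- "behavior"
    bd <- lapply(sessions, derive_behavior, immobile_cm_s = cfg$immobile_cm_s,
                 stationary_cm_s = cfg$stationary_cm_s)
    bundle$lap_summary <- do.call(rbind, lapply(seq_along(bd), function(i) {
      ls <- bd[[i]]$lap_summary
      ls$session_id <- sessions[[i]]$session_id
      ls
    }))

    stage <- "tuning"
    per_source <- list()
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      inc <- which(vapply(s$rois, function(r) isTRUE(!is.null(r$norm_q)),
                          logical(1)))
      for (j in inc) {
        r <- s$rois[[j]]
        entry <- list(session = i, roi_id = r$roi_id, source = s$source)
        entry$pos_fam <- try(bin_by_position(r$norm_q, s$behavior$position_cm,
                                             bd[[i]], "familiar",
                                             s$track_length_cm, cfg$pos_bin_cm),
                             silent = TRUE)
        entry$vel_fam <- try(bin_by_velocity(r$norm_q, bd[[i]], "familiar",
                                             cfg$vel_bin_cm_s, cfg$vel_range),
                             silent = TRUE)
        entry$onset <- try(align_to_motion_onset(r$norm_q, bd[[i]]$motion_onsets,
                                                 s$frame_rate_hz,
                                                 cfg$onset_window_s),
                           silent = TRUE)
        per_source[[length(per_source) + 1L]] <- entry
      }
    }
    bundle$roi_curves <- per_source

    stage <- "inference"
    ok_pos <- Filter(function(e) !inherits(e$pos_fam, "try-error"), per_source)
    ok_vel <- Filter(function(e) !inherits(e$vel_fam, "try-error"), per_source)
    fits <- list()
    if (length(ok_pos) >= 1L) {
      pp <- curve_population_points(lapply(ok_pos, function(e) {
        cv <- e$pos_fam
        cv$bin_centers <- cv$bin_centers_norm   # pool on normalised position
        cv
      }))
      fits$position_population <- try(fit_linear(pp$x, pp$y), silent = TRUE)
      roi_fits <- lapply(ok_pos, function(e) {
        p <- curve_roi_points(e$pos_fam)
        try(fit_linear(p$x, p$y), silent = TRUE)
      })
      roi_fits <- Filter(function(f) !inherits(f, "try-error"), roi_fits)
      fits$position_roi <- roi_fits
      fits$position_class <- classify_roi_fits(roi_fits, cfg$alpha)
    }
    if (length(ok_vel) >= 1L) {
      pv <- curve_population_points(lapply(ok_vel, `[[`, "vel_fam"))
      fits$velocity_population <- try(fit_linear(pv$x, pv$y), silent = TRUE)
      roi_fits <- lapply(ok_vel, function(e) {
        p <- curve_roi_points(e$vel_fam)
        try(fit_linear(p$x, p$y), silent = TRUE)
      })
      roi_fits <- Filter(function(f) !inherits(f, "try-error"), roi_fits)
      fits$velocity_roi <- roi_fits
      fits$velocity_class <- classify_roi_fits(roi_fits, cfg$alpha)
    }
    bundle$fits <- fits

    # cross-source resampling comparison (when both sources present)
    src <- vapply(per_source, `[[`, character(1), "source")
    if (length(unique(src)) == 2L) {
      tabulate_pts <- function(entries) lapply(entries, function(e) {
        cv <- e$pos_fam
        list(x = cv$bin_centers_norm, y = cv$mean)
      })
      n_by_src <- table(src)
      small <- names(which.min(n_by_src)); big <- names(which.max(n_by_src))
      small_pts <- tabulate_pts(Filter(function(e) e$source == small &&
                                         !inherits(e$pos_fam, "try-error"),
                                       per_source))
      big_pts <- tabulate_pts(Filter(function(e) e$source == big &&
                                       !inherits(e$pos_fam, "try-error"),
                                     per_source))
      if (length(small_pts) >= 1L && length(big_pts) > length(small_pts)) {
        ref <- fit_linear(unlist(lapply(small_pts, `[[`, "x")),
                          unlist(lapply(small_pts, `[[`, "y")))
        bundle$resample <- resample_comparison(
          big_pts, subsample_n = length(small_pts), reference_fit = ref,
          n_reps = cfg$resample_reps, seed = derive_seed(cfg$seed, 42))
      }
    }

    stage <- "novelty"
    novelty <- list()
    for (i in seq_along(sessions)) {
      s <- sessions[[i]]
      sched <- s$env_schedule
      if (!"novel" %in% sched$env_label) next
      ev <- sched$start_frame[sched$env_label == "novel"][1]
      inc <- which(vapply(s$rois, function(r) !is.null(r$norm_mean), logical(1)))
      if (length(inc) < 2L) next
      tr <- do.call(rbind, lapply(s$rois[inc], `[[`, "norm_mean"))
      al <- align_to_transition(tr, ev, s$frame_rate_hz)
      base <- shuffle_baseline(tr, subsample_n = nrow(tr),
                               n_shuffles = cfg$n_shuffles,
                               n_subsample_reps = cfg$n_subsample_reps,
                               frame_rate_hz = s$frame_rate_hz,
                               seed = derive_seed(cfg$seed, 100 + i))
      base_al <- list(mean = base$mean[al$orig_frames + 1L],
                      ci_lo = base$ci_lo[al$orig_frames + 1L],
                      ci_hi = base$ci_hi[al$orig_frames + 1L])
      class(base_al) <- "axonav_shuffle_baseline"
      runs <- detect_significant_runs(al$population_mean, base_al,
                                      min_run = 2L, s$frame_rate_hz)
      binned <- bin_aligned(al, "frames", cfg$frame_bin)
      lapb <- bin_aligned(al, "lap", lap_index = bd[[i]]$lap_index)
      # running-only variant (immobility <= stationary threshold removed)
      run_filt <- filter_frames_by_motion(list(), bd[[i]]$velocity_cm_s,
                                          "running", cfg$stationary_cm_s)
      al_run <- try(align_to_transition(tr, ev, s$frame_rate_hz,
                                        frame_index = run_filt$index),
                    silent = TRUE)
      novelty[[s$session_id]] <- list(
        session = s$session_id, event_frame = ev, aligned = al,
        baseline = base_al, runs = runs, binned_50 = binned,
        binned_lap = lapb,
        aligned_running = if (!inherits(al_run, "try-error")) al_run else NULL)
    }
    bundle$novelty <- novelty

    stage <- "behavior_anova"
    ls <- bundle$lap_summary
    novel_sessions <- vapply(sessions, function(s)
      "novel" %in% s$env_schedule$env_label, logical(1))
    if (any(novel_sessions) && nrow(ls)) {
      sub <- ls[!is.na(ls$mean_moving_velocity_cm_s), ]
      if (length(unique(sub$lap)) >= 2L && nrow(sub) >= 4L) {
        fam <- sub[sub$env == "familiar", ]
        ref_lap <- if (nrow(fam)) max(fam$lap) else NULL
        bundle$velocity_anova <- try(
          anova_tukey(sub$mean_moving_velocity_cm_s, sub$lap,
                      reference = ref_lap), silent = TRUE)
      }
    }

    stage <- "write"
    if (!is.null(out_dir)) export_bundle(bundle, out_dir)
    bundle
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stopf("pipeline failed at stage '%s': %s", stage,
          attr(res, "condition")$message %||% as.character(res))
  class(res) <- "axonav_results"
  res
}

#' Packaged demo pipeline configuration
#'
#' Two 5-minute familiar + 5-minute novel LC-like sessions with 10 axons and
#' 5 blebs each, reduced shuffle replicates, suitable for a quick
#' deterministic end-to-end run (~1 minute).
#'
#' @param seed root seed.
#' @return an [pipeline_config()].
#' @export
demo_config <- function(seed = 1L) {
  pipeline_config(
    sim = sim_config(n_sessions = 2, axons_per_session = 10,
                     blebs_per_session = 5, source = "LC",
                     familiar_duration_s = 300, novel_duration_s = 300),
    seed = seed, n_shuffles = 50L, n_subsample_reps = 50L,
    resample_reps = 200L)
}

# write the bundle as deterministic text files
export_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(bundle$qc_report))
    write_csv_det(bundle$qc_report, file.path(out_dir, "qc_report.csv"))
  if (!is.null(bundle$lap_summary))
    write_csv_det(bundle$lap_summary, file.path(out_dir, "lap_summary.csv"))
  if (!is.null(bundle$ground_truth))
    write_csv_det(bundle$ground_truth, file.path(out_dir, "ground_truth.csv"))

  fits <- bundle$fits
  if (length(fits)) {
    rows <- list()
    for (nm in c("position_population", "velocity_population")) {
      f <- fits[[nm]]
      if (!is.null(f) && !inherits(f, "try-error"))
        rows[[nm]] <- data.frame(fit = nm, slope = f$slope,
                                 intercept = f$intercept, F_stat = f$F_stat,
                                 p_value = f$p_value, n = f$n_points)
    }
    if (length(rows))
      write_csv_det(do.call(rbind, rows), file.path(out_dir, "population_fits.csv"))
    cls <- list()
    for (nm in c("position_class", "velocity_class")) {
      cc <- fits[[nm]]
      if (!is.null(cc))
        cls[[nm]] <- data.frame(measure = sub("_class", "", nm),
                                positive = cc$counts["positive"],
                                negative = cc$counts["negative"],
                                ns = cc$counts["ns"])
    }
    if (length(cls))
      write_csv_det(do.call(rbind, cls), file.path(out_dir, "roi_classification.csv"))
  }
  if (!is.null(bundle$resample)) {
    rs <- bundle$resample
    write_csv_det(data.frame(rep = seq_along(rs$slopes), slope = rs$slopes,
                             intercept = rs$intercepts),
                  file.path(out_dir, "resample_cloud.csv"))
  }
  for (nm in names(bundle$novelty)) {
    nv <- bundle$novelty[[nm]]
    write_csv_det(nv$runs$segments,
                  file.path(out_dir, paste0("novelty_runs_", nm, ".csv")))
    write_csv_det(data.frame(bin_start_frame = nv$binned_50$bin_label,
                             population_mean = nv$binned_50$population_mean),
                  file.path(out_dir, paste0("novelty_bins50_", nm, ".csv")))
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("axonav")),
    seed = bundle$config$seed,
    n_sessions = length(bundle$config$input_dirs %||% bundle$config$sim),
    alpha = bundle$config$alpha)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

#' Markdown summary of a results bundle
#'
#' One section per figure family: QC counts, behavioural laps, population
#' regressions with classifications, the resampling cloud, and the
#' switch-aligned novelty analysis with significant epochs.  Sections whose
#' results are absent are marked "not run".  Regeneration is deterministic.
#'
#' @param bundle an `axonav_results` from [run_pipeline()].
#' @param path optional file to write the markdown to.
#' @return the report lines, invisibly when written to file.
#' @export
make_report <- function(bundle, path = NULL) {
  L <- c("# axonav run report", "")
  qc <- bundle$qc_report
  L <- c(L, "## Quality control")
  if (!is.null(qc)) {
    L <- c(L, sprintf("- ROIs: %d (%d axons, %d blebs)", nrow(qc),
                      sum(qc$kind == "axon"), sum(qc$kind == "bleb")),
           sprintf("- passed SNR filter: %d/%d axons",
                   sum(qc$passed_snr & qc$kind == "axon"), sum(qc$kind == "axon")),
           sprintf("- sustained-shift exclusions: %d", sum(qc$shift_flag)),
           sprintf("- included in analysis: %d", sum(qc$included_final)), "")
  } else L <- c(L, "- not run", "")

  L <- c(L, "## Behaviour")
  ls <- bundle$lap_summary
  if (!is.null(ls)) {
    L <- c(L, sprintf("- laps: %d across %d session(s)", nrow(ls),
                      length(unique(ls$session_id))),
           sprintf("- mean moving velocity: %.2f cm/s",
                   mean(ls$mean_moving_velocity_cm_s, na.rm = TRUE)),
           sprintf("- mean freezing ratio: %.3f", mean(ls$freezing_ratio)), "")
  } else L <- c(L, "- not run", "")

  L <- c(L, "## Encoding regressions")
  fits <- bundle$fits
  if (length(fits)) {
    for (nm in c("position_population", "velocity_population")) {
      f <- fits[[nm]]
      if (!is.null(f) && !inherits(f, "try-error"))
        L <- c(L, sprintf("- %s: slope %.4f, F = %.2f, p = %.3g (n = %d points)",
                          sub("_population", "", nm), f$slope, f$F_stat,
                          f$p_value, f$n_points))
    }
    for (nm in c("position_class", "velocity_class")) {
      cc <- fits[[nm]]
      if (!is.null(cc))
        L <- c(L, sprintf("- %s per-ROI: %d positive / %d negative / %d ns",
                          sub("_class", "", nm), cc$counts["positive"],
                          cc$counts["negative"], cc$counts["ns"]))
    }
    L <- c(L, "")
  } else L <- c(L, "- not run", "")

  L <- c(L, "## Resampling comparison")
  if (!is.null(bundle$resample)) {
    rs <- bundle$resample
    L <- c(L, sprintf("- %d resamples at n = %d; slope 95%% box [%.4f, %.4f]; reference contained: %s",
                      rs$n_reps, rs$subsample_n, rs$slope_ci[1], rs$slope_ci[2],
                      rs$contained), "")
  } else L <- c(L, "- not run", "")

  L <- c(L, "## Novelty response")
  if (length(bundle$novelty)) {
    for (nm in names(bundle$novelty)) {
      nv <- bundle$novelty[[nm]]
      seg <- nv$runs$segments
      ev_col <- which(nv$aligned$time_s == 0) - 1L
      post <- seg[seg$start >= ev_col, , drop = FALSE]
      L <- c(L, sprintf("- %s: %d epoch(s) above the 95%% band (%d post-switch)%s",
                        nm, nrow(seg), nrow(post),
                        if (nrow(post)) sprintf(", first %.1f s after switch lasting %.1f s",
                                                (post$start[1] - ev_col) / 30,
                                                post$duration_s[1]) else ""))
    }
    L <- c(L, "")
  } else L <- c(L, "- not run", "")

  if (!is.null(path)) { writeLines(L, path); return(invisible(L)) }
  L
}
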