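#' Session, behaviour and ROI-trace containers
#'
#' A `session` bundles one imaging session: frame-synchronised behaviour
#' (track position, reward and teleport events), per-ROI fluorescence
#' traces with metadata, the environment schedule, and free-form session
#' metadata.  All per-frame vectors share one length `N`; frame indices are
#' 0-based and intervals half-open.
#'
#' @param session_id character scalar identifying the session.
#' @param source `"VTA"` or `"LC"`, the projection source of the imaged axons.
#' @param frame_rate_hz imaging frame rate in Hz (nominally 30).
#' @param track_length_cm virtual track length in cm (200 or 300).
#' @param env_schedule data.frame with columns `env_label`
#'   (`"dark"`/`"familiar"`/`"novel"`) and `start_frame` (0-based, strictly
#'   increasing, first row at frame 0).
#' @param behavior a [behavior_raw()] object.
#' @param rois list of [roi_trace()] objects.
#' @param meta named list of free-form metadata (mouse id, indicator, planes).
#' @return An object of class `"axonav_session"`.
#' @seealso [read_session()], [write_session()], [validate_session()]
#' @export
session <- function(session_id, source, frame_rate_hz, track_length_cm,
                    env_schedule, behavior, rois, meta = list()) {
  s <- structure(list(
    session_id = as.character(session_id),
    source = as.character(source),
    frame_rate_hz = as.numeric(frame_rate_hz),
    track_length_cm = as.numeric(track_length_cm),
    env_schedule = as.data.frame(env_schedule, stringsAsFactors = FALSE),
    behavior = behavior,
    rois = rois,
    meta = meta
  ), class = "axonav_session")
  s
}

#' @rdname session
#' @param position_cm per-frame track position in cm.
#' @param reward_frames sorted 0-based frame indices of reward delivery.
#' @param teleport_frames sorted 0-based frame indices of teleport-to-start.
#' @param valid per-frame logical, acquisition ok (default all `TRUE`).
#' @export
behavior_raw <- function(position_cm, reward_frames = integer(),
                         teleport_frames = integer(), valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(position_cm))
  structure(list(
    position_cm = as.numeric(position_cm),
    reward_frames = as.integer(reward_frames),
    teleport_frames = as.integer(teleport_frames),
    valid = as.logical(valid)
  ), class = "axonav_behavior_raw")
}

#' @rdname session
#' @param roi_id character ROI identifier.
#' @param kind `"axon"` or `"bleb"` (autofluorescent control structure).
#' @param raw_f per-frame raw fluorescence, arbitrary units.
#' @param merged_from character vector of source ROI ids when this ROI is a
#'   merge product, else empty.
#' @param ... optional derived traces (`dff_short`, `dff_long`, `norm_q`,
#'   `norm_mean`) and extra metadata (e.g. `plane`).
#' @export
roi_trace <- function(roi_id, kind, raw_f, merged_from = character(), ...) {
  extra <- list(...)
  structure(c(list(
    roi_id = as.character(roi_id),
    kind = as.character(kind),
    raw_f = as.numeric(raw_f),
    merged_from = as.character(merged_from)
  ), extra), class = "axonav_roi_trace")
}

#' @export
print.axonav_session <- function(x, ...) {
  n <- length(x$behavior$position_cm)
  cat(sprintf("<axonav_session> %s | source %s | %d frames @ %g Hz | %g cm track | %d ROIs\n",
              x$session_id, x$source, n, x$frame_rate_hz, x$track_length_cm,
              length(x$rois)))
  cat("  environments:", paste(sprintf("%s@%d", x$env_schedule$env_label,
                                       x$env_schedule$start_frame),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' Number of frames in a session
#' @param s a session.
#' @return integer frame count.
#' @export
n_frames <- function(s) length(s$behavior$position_cm)

#' Per-frame environment labels from the schedule
#' @param s a session.
#' @return character vector of length `n_frames(s)`.
#' @export
env_labels <- function(s) {
  n <- n_frames(s)
  sched <- s$env_schedule
  lab <- character(n)
  starts <- c(sched$start_frame, n)
  for (i in seq_len(nrow(sched))) {
    idx <- seq.int(starts[i] + 1L, starts[i + 1L])
    if (starts[i] < starts[i + 1L]) lab[idx] <- sched$env_label[i]
  }
  lab
}

#' Validate a session against its invariants
#'
#' Checks every structural invariant (shared frame count, event indices in
#' range, position within the track, schedule ordering) and returns a report
#' rather than raising, so callers can decide how to react.
#'
#' @param s a [session()].
#' @return data.frame with columns `code` and `message`; zero rows means valid.
#' @export
validate_session <- function(s) {
  bad <- list()
  add <- function(code, msg) bad[[length(bad) + 1L]] <<- data.frame(
    code = code, message = msg, stringsAsFactors = FALSE)

  n <- length(s$behavior$position_cm)
  if (!is.numeric(s$frame_rate_hz) || s$frame_rate_hz <= 0)
    add("frame_rate", sprintf("frame_rate_hz must be > 0, got %s", s$frame_rate_hz))
  if (!is.numeric(s$track_length_cm) || s$track_length_cm <= 0)
    add("track_length", sprintf("track_length_cm must be > 0, got %s", s$track_length_cm))

  b <- s$behavior
  if (length(b$valid) != n)
    add("length_valid", sprintf("valid has length %d, expected %d", length(b$valid), n))
  pos_bad <- which(b$position_cm < 0 | b$position_cm > s$track_length_cm)
  if (length(pos_bad))
    add("position_range", sprintf("position_cm outside [0, %g] at %d frame(s), first at frame %d (value %g)",
                                  s$track_length_cm, length(pos_bad), pos_bad[1] - 1L,
                                  b$position_cm[pos_bad[1]]))
  for (ev in c("reward_frames", "teleport_frames")) {
    fr <- b[[ev]]
    if (length(fr) && (any(fr < 0L) || any(fr >= n)))
      add(paste0(ev, "_range"), sprintf("%s contains index outside [0, %d)", ev, n))
    if (is.unsorted(fr, strictly = TRUE) && length(fr) > 1L)
      add(paste0(ev, "_order"), sprintf("%s not strictly increasing", ev))
  }

  sched <- s$env_schedule
  if (!nrow(sched)) {
    add("schedule_empty", "env_schedule has no rows")
  } else {
    if (sched$start_frame[1] != 0L)
      add("schedule_start", sprintf("env_schedule must start at frame 0, got %d", sched$start_frame[1]))
    if (nrow(sched) > 1L && any(diff(sched$start_frame) <= 0))
      add("schedule_order", "env_schedule start_frames not strictly increasing")
    if (!all(sched$env_label %in% c("dark", "familiar", "novel")))
      add("schedule_label", "env_label must be one of dark/familiar/novel")
  }

  if (!s$source %in% c("VTA", "LC"))
    add("source", sprintf("source must be VTA or LC, got %s", s$source))

  ids <- vapply(s$rois, function(r) r$roi_id, character(1))
  if (anyDuplicated(ids))
    add("roi_ids", "duplicate roi_id in rois")
  for (r in s$rois) {
    if (length(r$raw_f) != n)
      add("length_trace", sprintf("ROI %s raw_f has length %d, expected %d",
                                  r$roi_id, length(r$raw_f), n))
    if (anyNA(r$raw_f) || any(!is.finite(r$raw_f)))
      add("trace_finite", sprintf("ROI %s raw_f contains non-finite values", r$roi_id))
    if (!r$kind %in% c("axon", "bleb"))
      add("roi_kind", sprintf("ROI %s kind must be axon or bleb, got %s", r$roi_id, r$kind))
    for (d in c("dff_short", "dff_long", "norm_q", "norm_mean")) {
      if (!is.null(r[[d]]) && length(r[[d]]) != n)
        add("length_derived", sprintf("ROI %s %s has length %d, expected %d",
                                      r$roi_id, d, length(r[[d]]), n))
    }
  }
  if (length(bad)) do.call(rbind, bad) else
    data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
}

derived_trace_names <- c("dff_short", "dff_long", "norm_q", "norm_mean")

#' Write a session to a directory
#'
#' The on-disk layout is plain text and diffable: `behavior.csv` (frame,
#' position_cm, reward, teleport, env_label, valid), `traces.csv` (frame plus
#' one raw-F column per ROI), `derived.csv` (optional, computed traces),
#' `rois.json` and `session.json`.  Numbers are written with `%.17g` so the
#' representation round-trips doubles exactly and identical sessions produce
#' byte-identical files.
#'
#' @param s a valid [session()].
#' @param path directory to create/write into.
#' @return `invisible(path)`.
#' @export
write_session <- function(s, path) {
  rep <- validate_session(s)
  if (nrow(rep))
    stopf("refusing to write invalid session: %s", paste(rep$code, collapse = ", "))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  n <- n_frames(s)
  b <- s$behavior

  reward <- integer(n); reward[b$reward_frames + 1L] <- 1L
  teleport <- integer(n); teleport[b$teleport_frames + 1L] <- 1L
  beh_lines <- c("frame,position_cm,reward,teleport,env_label,valid",
                 paste(0:(n - 1L), fmt_num(b$position_cm), reward, teleport,
                       env_labels(s), as.integer(b$valid), sep = ","))
  writeLines(beh_lines, file.path(path, "behavior.csv"))

  ids <- vapply(s$rois, function(r) r$roi_id, character(1))
  tr <- vapply(s$rois, function(r) fmt_num(r$raw_f), character(n))
  if (is.null(dim(tr))) tr <- matrix(tr, nrow = n)
  tr_lines <- c(paste(c("frame", ids), collapse = ","),
                do.call(paste, c(list(0:(n - 1L)), asplit(tr, 2), sep = ",")))
  writeLines(tr_lines, file.path(path, "traces.csv"))

  # derived traces, one column per (roi, trace-name) actually computed
  dcols <- list(); dnames <- character()
  for (r in s$rois) for (d in derived_trace_names) {
    if (!is.null(r[[d]])) {
      dcols[[length(dcols) + 1L]] <- fmt_num(r[[d]])
      dnames <- c(dnames, paste0(r$roi_id, ".", d))
    }
  }
  if (length(dcols)) {
    d_lines <- c(paste(c("frame", dnames), collapse = ","),
                 do.call(paste, c(list(0:(n - 1L)), dcols, sep = ",")))
    writeLines(d_lines, file.path(path, "derived.csv"))
  }

  roi_meta <- lapply(s$rois, function(r) {
    keep <- setdiff(names(r), c("raw_f", derived_trace_names))
    r[keep]
  })
  writeLines(jsonlite::toJSON(roi_meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(path, "rois.json"))
  sess_meta <- list(
    session_id = s$session_id, source = s$source,
    frame_rate_hz = s$frame_rate_hz, track_length_cm = s$track_length_cm,
    env_schedule = s$env_schedule, meta = s$meta)
  writeLines(jsonlite::toJSON(sess_meta, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, dataframe = "rows"),
             file.path(path, "session.json"))
  invisible(path)
}

#' Read a session from a directory written by [write_session()]
#'
#' @param path directory containing `behavior.csv`, `traces.csv`,
#'   `rois.json`, `session.json` (and optionally `derived.csv`).
#' @return a validated [session()]; unknown metadata keys are preserved.
#' @export
read_session <- function(path) {
  need <- c("behavior.csv", "traces.csv", "rois.json", "session.json")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stopf("cannot load session: missing file '%s' in %s", f, path)
  }
  meta <- jsonlite::fromJSON(file.path(path, "session.json"),
                             simplifyDataFrame = TRUE)
  beh <- read.csv(file.path(path, "behavior.csv"), stringsAsFactors = FALSE)
  tr <- read.csv(file.path(path, "traces.csv"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (nrow(beh) != nrow(tr))
    stopf("validation error: behavior has %d rows but traces has %d rows",
          nrow(beh), nrow(tr))
  roi_meta <- jsonlite::fromJSON(file.path(path, "rois.json"),
                                 simplifyDataFrame = FALSE)
  derived <- NULL
  if (file.exists(file.path(path, "derived.csv")))
    derived <- read.csv(file.path(path, "derived.csv"), check.names = FALSE,
                        stringsAsFactors = FALSE)

  b <- behavior_raw(
    position_cm = beh$position_cm,
    reward_frames = beh$frame[beh$reward == 1L],
    teleport_frames = beh$frame[beh$teleport == 1L],
    valid = as.logical(beh$valid))
  rois <- lapply(roi_meta, function(m) {
    id <- m$roi_id
    if (!id %in% names(tr))
      stopf("validation error: ROI '%s' in rois.json has no column in traces.csv", id)
    extra <- m[setdiff(names(m), c("roi_id", "kind", "merged_from"))]
    r <- do.call(roi_trace, c(list(
      roi_id = id, kind = m$kind, raw_f = tr[[id]],
      merged_from = unlist(m$merged_from) %||% character()), extra))
    if (!is.null(derived)) {
      for (d in derived_trace_names) {
        col <- paste0(id, ".", d)
        if (col %in% names(derived)) r[[d]] <- derived[[col]]
      }
    }
    r
  })
  sched <- as.data.frame(meta$env_schedule, stringsAsFactors = FALSE)
  sched$start_frame <- as.integer(sched$start_frame)
  s <- session(meta$session_id, meta$source, meta$frame_rate_hz,
               meta$track_length_cm, sched, b, rois,
               meta = meta$meta %||% list())
  rep <- validate_session(s)
  if (nrow(rep))
    stopf("validation error reading %s: %s", path,
          paste(rep$message, collapse = "; "))
  s
}
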