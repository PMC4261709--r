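# Recording-bundle layout and core containers.
#
# A "recording bundle" is one play session on disk:
#   sensorA/skeleton.xml        tracked upper-body joints, sensor clock
#   sensorA/audio.wav           mono PCM16
#   sensorA/source_angle.xml    audio source azimuth stream (degrees)
#   sensorA/calibration.xml     chessboard corner coordinates, sensor frame
#   sensorA/image_timestamps.xml
#   sensorB/...                 same five files
#   manifest.yaml               phase plan, seat layout, participants
#   ground_truth.yaml (+ ground_truth_tracks.csv)   synthetic bundles only
#
# All coordinates are meters, angles degrees, times float seconds on the
# owning sensor's free-running clock (the clock starts when the device is
# connected; a shared hand clap later defines the common world clock).

#' The ten tracked upper-body joints
#'
#' Seated participants are tracked with the upper body only; every skeleton
#' frame keys exactly these ten joints.
#'
#' @return character vector of length 10.
#' @export
joint_ids <- function() {
  c("head", "shoulder_center", "shoulder_left", "shoulder_right",
    "elbow_left", "elbow_right", "wrist_left", "wrist_right",
    "hand_left", "hand_right")
}

TRACK_STATES <- c("tracked", "inferred", "missing")

#' Construct a skeleton stream
#'
#' A stream is the time-ordered sequence of frames for one sensor-local
#' person slot: an `n x 10 x 3` position array (meters), an `n x 10`
#' tracking-state matrix and the frame timestamps (seconds, sensor clock).
#' Positions of `missing` joints are `NA`.
#'
#' @param time numeric vector, non-decreasing, finite, non-negative.
#' @param pos `n x 10 x 3` array; joint dimension ordered as [joint_ids()].
#' @param state `n x 10` character matrix of tracked/inferred/missing,
#'   or `NULL` for all-tracked.
#' @param slot sensor-local person slot index (integer).
#' @return object of class `skeleton_stream`.
#' @export
skeleton_stream <- function(time, pos, state = NULL, slot = 0L) {
  n <- length(time)
  if (n == 0L) {
    pos <- array(numeric(0), dim = c(0L, 10L, 3L))
    state <- matrix(character(0), 0L, 10L)
  }
  stopifnot(is.numeric(time), identical(dim(pos)[1], as.integer(n)),
            dim(pos)[2] == 10L, dim(pos)[3] == 3L)
  if (n > 0 && any(!is.finite(time)))
    abort_dyadscope("ParseError", "skeleton timestamps must be finite")
  if (n > 1 && any(diff(time) < 0))
    abort_dyadscope("ParseError", "skeleton timestamps must be non-decreasing")
  if (is.null(state)) state <- matrix("tracked", n, 10L)
  stopifnot(all(state %in% TRACK_STATES))
  if (any(!is.finite(pos[, , 1]) & state != "missing"))
    abort_dyadscope("ParseError", "non-missing joints must have finite positions")
  dimnames(pos) <- list(NULL, joint_ids(), c("x", "y", "z"))
  colnames(state) <- joint_ids()
  structure(list(time = as.numeric(time), pos = pos, state = state,
                 slot = as.integer(slot)),
            class = "skeleton_stream")
}

#' @export
print.skeleton_stream <- function(x, ...) {
  cat(sprintf("<skeleton_stream> slot %d, %d frames, span [%.2f, %.2f] s\n",
              x$slot, length(x$time),
              if (length(x$time)) min(x$time) else NA_real_,
              if (length(x$time)) max(x$time) else NA_real_))
  invisible(x)
}

#' Construct a sensor recording
#'
#' Everything one depth sensor saved for a session, still on its own clock
#' and in its own coordinate frame.
#'
#' @param sensor_id `"A"` or `"B"`.
#' @param skeletons list of [skeleton_stream()], one per tracked person slot.
#' @param audio list with `samples` (numeric, full-scale \[-1,1\]) and `rate` (Hz).
#' @param source_angle data.frame with columns `time` (s) and `azimuth`
#'   (degrees, 0 along the sensor optical axis, positive to the sensor's left).
#' @param calibration list with `points` (ordered `n x 3` chessboard-corner
#'   matrix, row-major over the grid), `rows`, `cols`, `spacing` (m).
#' @param image_timestamps numeric vector of video frame times (the video
#'   files themselves are opaque and not carried).
#' @param audio_start sensor-clock time of the first audio sample.
#' @return object of class `sensor_recording`.
#' @export
sensor_recording <- function(sensor_id, skeletons, audio, source_angle,
                             calibration = NULL, image_timestamps = numeric(),
                             audio_start = 0) {
  stopifnot(sensor_id %in% c("A", "B"), is.list(skeletons),
            is.numeric(audio$samples), audio$rate > 0)
  audio$rate <- as.integer(audio$rate)
  if (!is.null(calibration)) {
    stopifnot(is.matrix(calibration$points), ncol(calibration$points) == 3L)
    if (nrow(calibration$points) < 6L)
      abort_dyadscope("DegenerateConfiguration",
                      "calibration requires at least 6 chessboard points")
  }
  structure(list(sensor_id = sensor_id, skeletons = skeletons, audio = audio,
                 source_angle = source_angle, calibration = calibration,
                 image_timestamps = as.numeric(image_timestamps),
                 audio_start = as.numeric(audio_start)),
            class = "sensor_recording")
}

#' Construct a session manifest
#'
#' @param phases data.frame with `name` and `duration` (seconds, > 0). The
#'   protocol default is free interactive play (240 s), directed game
#'   (120 s), free play while the parent is occupied (120 s).
#' @param seats named list `parent`/`child`, each a 3-vector (meters, world
#'   frame; the table center is the world origin).
#' @param participants named list `parent`/`child` of metadata lists
#'   (e.g. `age_months`, `pirgas`).
#' @return object of class `session_manifest`.
#' @export
session_manifest <- function(phases, seats, participants = NULL) {
  stopifnot(is.data.frame(phases), all(c("name", "duration") %in% names(phases)))
  if (any(phases$duration <= 0))
    abort_dyadscope("ParseError", "phase durations must be > 0")
  stopifnot(setequal(names(seats), c("parent", "child")),
            length(seats$parent) == 3L, length(seats$child) == 3L)
  if (is.null(participants))
    participants <- list(parent = list(role = "parent"),
                         child = list(role = "child"))
  structure(list(phases = phases,
                 seats = lapply(seats, as.numeric),
                 table_center = c(0, 0, 0),
                 participants = participants),
            class = "session_manifest")
}

# ---- XML dialect -----------------------------------------------------------

fmt_num <- function(x, digits = 9) {
  out <- sprintf(paste0("%.", digits, "f"), x)
  out[!is.finite(x)] <- "nan"
  out
}

write_skeleton_xml <- function(skeletons, sensor_id, path) {
  lines <- c('<?xml version="1.0"?>',
             sprintf('<skeletons sensor="%s">', sensor_id))
  for (st in skeletons) {
    n <- length(st$time)
    if (n == 0L) next
    jid <- rep(joint_ids(), n)
    px <- as.vector(t(st$pos[, , 1, drop = TRUE]))
    py <- as.vector(t(st$pos[, , 2, drop = TRUE]))
    pz <- as.vector(t(st$pos[, , 3, drop = TRUE]))
    if (n == 1L) { px <- st$pos[1, , 1]; py <- st$pos[1, , 2]; pz <- st$pos[1, , 3] }
    jl <- sprintf('    <j id="%s" s="%s" x="%s" y="%s" z="%s"/>',
                  jid, as.vector(t(st$state)), fmt_num(px), fmt_num(py), fmt_num(pz))
    jg <- split(jl, rep(seq_len(n), each = 10L))
    fr <- sprintf('  <frame t="%s" slot="%d">', fmt_num(st$time, 6), st$slot)
    body <- unlist(lapply(seq_len(n), function(i) c(fr[i], jg[[i]], "  </frame>")),
                   use.names = FALSE)
    lines <- c(lines, body)
  }
  lines <- c(lines, "</skeletons>")
  writeLines(lines, path)
}

read_skeleton_xml <- function(path) {
  doc <- xml2::read_xml(path)
  frames <- xml2::xml_find_all(doc, ".//frame")
  nf <- length(frames)
  if (nf == 0L) return(list())
  t_all <- as.numeric(xml2::xml_attr(frames, "t"))
  slot_all <- as.integer(xml2::xml_attr(frames, "slot"))
  if (any(is.na(t_all)) || any(t_all < 0))
    abort_dyadscope("ParseError",
      sprintf("%s: malformed or negative frame timestamp", path))
  joints <- xml2::xml_find_all(doc, ".//frame/j")
  if (length(joints) != 10L * nf)
    abort_dyadscope("ParseError",
      sprintf("%s: expected 10 joints per frame, got %d joints for %d frames",
              path, length(joints), nf))
  ids <- xml2::xml_attr(joints, "id")
  if (!identical(ids, rep(joint_ids(), nf)))
    abort_dyadscope("ParseError", sprintf("%s: joint ids out of canonical order", path))
  s <- xml2::xml_attr(joints, "s")
  xs <- as.numeric(xml2::xml_attr(joints, "x"))
  ys <- as.numeric(xml2::xml_attr(joints, "y"))
  zs <- as.numeric(xml2::xml_attr(joints, "z"))
  xs[is.nan(xs)] <- NA_real_; ys[is.nan(ys)] <- NA_real_; zs[is.nan(zs)] <- NA_real_
  out <- list()
  for (sl in sort(unique(slot_all))) {
    sel <- which(slot_all == sl)
    if (any(diff(t_all[sel]) < 0))
      abort_dyadscope("ParseError",
        sprintf("%s: decreasing timestamps in slot %d (frame %d)",
                path, sl, sel[which(diff(t_all[sel]) < 0)[1] + 1L]))
    jsel <- as.vector(t(outer(sel - 1L, 1:10, function(a, b) a * 10L + b)))
    n <- length(sel)
    pos <- array(NA_real_, dim = c(n, 10L, 3L))
    pos[, , 1] <- matrix(xs[jsel], n, 10L, byrow = TRUE)
    pos[, , 2] <- matrix(ys[jsel], n, 10L, byrow = TRUE)
    pos[, , 3] <- matrix(zs[jsel], n, 10L, byrow = TRUE)
    out[[length(out) + 1L]] <-
      skeleton_stream(t_all[sel], pos,
                      matrix(s[jsel], n, 10L, byrow = TRUE), slot = sl)
  }
  out
}

write_angle_xml <- function(source_angle, sensor_id, path) {
  lines <- c('<?xml version="1.0"?>',
             sprintf('<source_angles sensor="%s">', sensor_id),
             sprintf('  <s t="%s" az="%s"/>',
                     fmt_num(source_angle$time, 6),
                     fmt_num(source_angle$azimuth, 4)),
             "</source_angles>")
  if (nrow(source_angle) == 0L) lines <- lines[-3L]
  writeLines(lines, path)
}

read_angle_xml <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, ".//s")
  tm <- as.numeric(xml2::xml_attr(nodes, "t"))
  az <- as.numeric(xml2::xml_attr(nodes, "az"))
  if (any(is.na(tm)))
    abort_dyadscope("ParseError", sprintf("%s: malformed angle timestamp", path))
  if (length(tm) > 1 && any(diff(tm) < 0))
    abort_dyadscope("ParseError", sprintf("%s: decreasing angle timestamps", path))
  data.frame(time = tm, azimuth = az)
}

write_calibration_xml <- function(calibration, sensor_id, path) {
  hdr <- sprintf('<calibration sensor="%s" rows="%d" cols="%d" spacing="%s">',
                 sensor_id, calibration$rows, calibration$cols,
                 fmt_num(calibration$spacing, 6))
  pts <- sprintf('  <p x="%s" y="%s" z="%s"/>',
                 fmt_num(calibration$points[, 1]),
                 fmt_num(calibration$points[, 2]),
                 fmt_num(calibration$points[, 3]))
  writeLines(c('<?xml version="1.0"?>', hdr, pts, "</calibration>"), path)
}

read_calibration_xml <- function(path) {
  doc <- xml2::read_xml(path)
  root <- xml2::xml_root(doc)
  nodes <- xml2::xml_find_all(doc, ".//p")
  pts <- cbind(as.numeric(xml2::xml_attr(nodes, "x")),
               as.numeric(xml2::xml_attr(nodes, "y")),
               as.numeric(xml2::xml_attr(nodes, "z")))
  if (length(nodes) > 0 && any(is.na(pts)))
    abort_dyadscope("ParseError", sprintf("%s: malformed calibration point", path))
  list(points = pts,
       rows = as.integer(xml2::xml_attr(root, "rows")),
       cols = as.integer(xml2::xml_attr(root, "cols")),
       spacing = as.numeric(xml2::xml_attr(root, "spacing")))
}

write_timestamps_xml <- function(times, sensor_id, path) {
  lines <- c('<?xml version="1.0"?>',
             sprintf('<image_timestamps sensor="%s">', sensor_id),
             sprintf('  <i t="%s"/>', fmt_num(times, 6)),
             "</image_timestamps>")
  if (length(times) == 0L) lines <- lines[-3L]
  writeLines(lines, path)
}

read_timestamps_xml <- function(path) {
  doc <- xml2::read_xml(path)
  tm <- as.numeric(xml2::xml_attr(xml2::xml_find_all(doc, ".//i"), "t"))
  if (any(is.na(tm)))
    abort_dyadscope("ParseError", sprintf("%s: malformed image timestamp", path))
  tm
}

# ---- bundle ----------------------------------------------------------------

SENSOR_FILES <- c("skeleton.xml", "audio.wav", "source_angle.xml",
                  "calibration.xml", "image_timestamps.xml")

manifest_to_list <- function(manifest) {
  list(phases = lapply(seq_len(nrow(manifest$phases)), function(i)
         list(name = manifest$phases$name[i],
              duration = manifest$phases$duration[i])),
       seats = lapply(manifest$seats, as.list),
       table_center = as.list(manifest$table_center),
       participants = manifest$participants)
}

manifest_from_list <- function(x) {
  phases <- data.frame(
    name = vapply(x$phases, function(p) p$name, ""),
    duration = vapply(x$phases, function(p) as.numeric(p$duration), 0))
  session_manifest(phases,
                   seats = lapply(x$seats, function(s) unlist(s, use.names = FALSE)),
                   participants = x$participants)
}

#' Write a recording bundle to disk
#'
#' Produces the on-disk layout read by [read_bundle()]. Writing is
#' deterministic: identical inputs yield byte-identical files.
#'
#' @param recordings named list with elements `A` and `B`, each a
#'   [sensor_recording()].
#' @param manifest a [session_manifest()].
#' @param path destination directory (created if needed).
#' @param ground_truth optional synthetic ground truth (see
#'   [generate_recording()]); written to `ground_truth.yaml` plus a
#'   `ground_truth_tracks.csv` companion for the per-tick joint tracks.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(recordings, manifest, path, ground_truth = NULL) {
  stopifnot(setequal(names(recordings), c("A", "B")))
  ok <- dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    abort_dyadscope("IOFailure", sprintf("cannot create directory '%s'", path))
  for (sid in c("A", "B")) {
    rec <- recordings[[sid]]
    sdir <- file.path(path, paste0("sensor", sid))
    dir.create(sdir, showWarnings = FALSE)
    write_skeleton_xml(rec$skeletons, sid, file.path(sdir, "skeleton.xml"))
    write_wav(rec$audio$samples, rec$audio$rate, file.path(sdir, "audio.wav"))
    write_angle_xml(rec$source_angle, sid, file.path(sdir, "source_angle.xml"))
    write_calibration_xml(rec$calibration, sid, file.path(sdir, "calibration.xml"))
    write_timestamps_xml(rec$image_timestamps, sid,
                         file.path(sdir, "image_timestamps.xml"))
  }
  yaml::write_yaml(manifest_to_list(manifest), file.path(path, "manifest.yaml"),
                   precision = 12L)
  if (!is.null(ground_truth)) {
    gt <- ground_truth
    tracks <- gt$tracks
    gt$tracks <- NULL
    yaml::write_yaml(gt, file.path(path, "ground_truth.yaml"), precision = 12L)
    if (!is.null(tracks))
      utils::write.csv(tracks, file.path(path, "ground_truth_tracks.csv"),
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a recording bundle from disk
#'
#' @param path bundle directory written by [write_bundle()] (or the
#'   acquisition application's equivalent).
#' @return list with `recordings` (named list `A`, `B`), `manifest`, and
#'   `ground_truth` (`NULL` unless the bundle is synthetic).
#' @export
read_bundle <- function(path) {
  if (!dir.exists(path))
    abort_dyadscope("BundleIncomplete", sprintf("bundle directory '%s' not found", path))
  wanted <- c(file.path(rep(c("sensorA", "sensorB"), each = 5L),
                        rep(SENSOR_FILES, 2L)), "manifest.yaml")
  missing <- wanted[!file.exists(file.path(path, wanted))]
  if (length(missing))
    abort_dyadscope("BundleIncomplete",
      sprintf("bundle '%s' is missing: %s", path, paste(missing, collapse = ", ")))
  known <- c(wanted, "ground_truth.yaml", "ground_truth_tracks.csv")
  extra <- setdiff(list.files(path, recursive = TRUE), known)
  if (length(extra))
    message("read_bundle: ignoring unknown files: ", paste(extra, collapse = ", "))
  recs <- list()
  for (sid in c("A", "B")) {
    sdir <- file.path(path, paste0("sensor", sid))
    audio <- read_wav(file.path(sdir, "audio.wav"))
    recs[[sid]] <- sensor_recording(
      sensor_id = sid,
      skeletons = read_skeleton_xml(file.path(sdir, "skeleton.xml")),
      audio = audio,
      source_angle = read_angle_xml(file.path(sdir, "source_angle.xml")),
      calibration = read_calibration_xml(file.path(sdir, "calibration.xml")),
      image_timestamps = read_timestamps_xml(file.path(sdir, "image_timestamps.xml")))
  }
  manifest <- manifest_from_list(yaml::read_yaml(file.path(path, "manifest.yaml")))
  gt <- NULL
  if (file.exists(file.path(path, "ground_truth.yaml"))) {
    gt <- yaml::read_yaml(file.path(path, "ground_truth.yaml"))
    tr <- file.path(path, "ground_truth_tracks.csv")
    if (file.exists(tr)) gt$tracks <- utils::read.csv(tr)
  }
  list(recordings = recs, manifest = manifest, ground_truth = gt)
}

# ---- resampling ------------------------------------------------------------

#' Build a uniform world clock
#'
#' @param start,end span in seconds.
#' @param rate ticks per second (default 30, the sensors' nominal frame rate).
#' @return numeric vector of tick times.
#' @export
make_clock <- function(start, end, rate = 30) {
  if (end < start) abort_dyadscope("EmptyClock", "clock end precedes start")
  seq(start, end, by = 1 / rate)
}

# Nearest sample index for each clock tick; NA where no sample lies within
# max_gap. Never interpolates.
nearest_index <- function(time, clock, max_gap) {
  n <- length(time)
  if (n == 0L) return(rep(NA_integer_, length(clock)))
  lo <- findInterval(clock, time)
  lo_ok <- lo >= 1L
  hi <- pmin(lo + 1L, n)
  lo[!lo_ok] <- 1L
  d_lo <- abs(clock - time[lo])
  d_hi <- abs(time[hi] - clock)
  idx <- ifelse(d_lo <= d_hi, lo, hi)
  gap <- abs(time[idx] - clock) > max_gap + 1e-12
  idx[gap] <- NA_integer_
  idx
}

#' Resample a timestamped stream onto a uniform clock
#'
#' Nearest-neighbour resampling with an explicit gap mask: each clock tick
#' takes the nearest-in-time sample when one lies within `max_gap`,
#' otherwise the tick is a gap. Values are never interpolated, so every
#' emitted sample equals some input sample exactly; figure-style blank
#' regions survive as gaps.
#'
#' @param time sample timestamps (non-decreasing).
#' @param values numeric vector, matrix or 3-d array (first dimension =
#'   samples).
#' @param clock uniform tick times from [make_clock()].
#' @param max_gap maximum tick-to-sample distance in seconds (default 0.05,
#'   i.e. 1.5 frame periods at 30 Hz).
#' @return list with `values` (same shape, first dimension = ticks, `NA` in
#'   gaps), `gap` (logical per tick) and `index` (source sample per tick).
#' @export
resample_to_clock <- function(time, values, clock, max_gap = 0.05) {
  if (length(clock) == 0L) abort_dyadscope("EmptyClock", "empty clock")
  if (length(time) > 1 && any(diff(time) < 0))
    abort_dyadscope("ParseError", "stream timestamps must be non-decreasing")
  if (length(time) == 0L) {
    shape <- dim(values)
    if (is.null(shape)) out <- rep(NA_real_, length(clock))
    else out <- array(NA_real_, dim = c(length(clock), shape[-1]))
    return(list(values = out, gap = rep(TRUE, length(clock)),
                index = rep(NA_integer_, length(clock))))
  }
  idx <- nearest_index(time, clock, max_gap)
  gap <- is.na(idx)
  take <- ifelse(gap, 1L, idx)   # placeholder row, blanked below
  if (is.null(dim(values))) {
    out <- values[take]
    out[gap] <- NA
  } else if (length(dim(values)) == 2L) {
    out <- values[take, , drop = FALSE]
    out[gap, ] <- NA
  } else {
    out <- values[take, , , drop = FALSE]
    out[gap, , ] <- NA
  }
  list(values = out, gap = gap, index = idx)
}
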