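# End-to-end orchestration: calibrate -> synchronise -> label -> clean ->
# fuse -> smooth -> features -> audio -> per-phase summaries, plus a
# figure-style report. Summary numbers are computed once here; the report
# only reads them.

#' Default pipeline configuration
#'
#' Every threshold used anywhere downstream, with its unit. Values mirror
#' the package defaults documented on each function.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(clock_rate = 30,            # Hz, common world clock
       max_gap = 0.05,             # s, resampling gap tolerance
       smooth_window = 5,          # frames, odd
       max_disagreement = 0.10,    # m, inter-sensor fusion tolerance
       max_jump = 0.5,             # m, inconsistent-skeleton rule (a)
       jump_dt = 0.1,              # s
       shoulder_range = c(0.15, 0.75),  # m, rule (b)
       seat_radius = 1.5,          # m, rule (c)
       contact_threshold = 0.10,   # m
       contact_hysteresis = 0.02,  # m
       contact_debounce = 0.25,    # s
       contribution_window = 1.0,  # s, trailing
       vad_frame = 0.025, vad_hop = 0.010,  # s
       azimuth_tolerance = 15, azimuth_margin = 5,  # degrees
       planar = FALSE)             # distances in the horizontal plane only
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    e$stage <- stage
    e$message <- sprintf("[stage %s] %s", stage, conditionMessage(e))
    stop(e)
  })
}

# Split one sensor's streams into per-role world-frame streams using the
# identity assignment, keeping only frames with that role.
role_stream <- function(skeletons, assignment, role) {
  parts <- list()
  for (st in skeletons) {
    r <- frame_roles(st, assignment)
    sel <- which(!is.na(r) & r == role)
    if (length(sel))
      parts[[length(parts) + 1L]] <-
        list(time = st$time[sel], pos = st$pos[sel, , , drop = FALSE],
             state = st$state[sel, , drop = FALSE])
  }
  if (length(parts) == 0L) return(NULL)
  time <- unlist(lapply(parts, `[[`, "time"))
  ord <- order(time)
  pos <- do.call(abind3, lapply(parts, `[[`, "pos"))
  state <- do.call(rbind, lapply(parts, `[[`, "state"))
  skeleton_stream(time[ord], pos[ord, , , drop = FALSE],
                  state[ord, , drop = FALSE], slot = 0L)
}

# rbind for n x 10 x 3 arrays along the first dimension.
abind3 <- function(...) {
  parts <- list(...)
  n <- sum(vapply(parts, function(p) dim(p)[1], 0L))
  out <- array(NA_real_, c(n, 10L, 3L))
  at <- 0L
  for (p in parts) {
    k <- dim(p)[1]
    if (k) out[at + seq_len(k), , ] <- p
    at <- at + k
  }
  out
}

#' Run the full analysis pipeline on a recording bundle
#'
#' @param bundle a bundle directory path, or the in-memory list returned
#'   by [read_bundle()] / [generate_recording()].
#' @param config a [default_config()] list (partial overrides allowed).
#' @param out_dir optional directory for CSV outputs (`dyad_series.csv`,
#'   `features.csv`, `summary.csv`, `events.csv`, `utterances.csv`,
#'   `audio_activity.csv`, `calibration_result.yaml`, `rejections.log`).
#' @return list with calibration, sync, identity, dyad series, features,
#'   events, audio activity, utterances, turn count, phases and summary.
#' @export
run_pipeline <- function(bundle, config = default_config(), out_dir = NULL) {
  config <- utils::modifyList(default_config(), config)
  if (is.character(bundle)) bundle <- run_stage("read", read_bundle(bundle))
  recA <- bundle$recordings$A
  recB <- bundle$recordings$B
  manifest <- bundle$manifest

  calA <- run_stage("calibrate", calibrate_sensor(recA$calibration))
  calB <- run_stage("calibrate", calibrate_sensor(recB$calibration))

  sync <- run_stage("synchronise", sync_from_clap(recA, recB))
  recB <- align_clocks(sync, recB)
  # world clock zero at the clap
  recA <- shift_recording(recA, -sync$clap_time_A)
  recB <- shift_recording(recB, -sync$clap_time_A)

  recA$skeletons <- lapply(recA$skeletons, function(s)
    apply_transform(calA$transform, s))
  recB$skeletons <- lapply(recB$skeletons, function(s)
    apply_transform(calB$transform, s))

  idA <- run_stage("label", assign_identity(recA$skeletons, manifest$seats))
  idB <- run_stage("label", assign_identity(recB$skeletons, manifest$seats))

  rejections <- list()
  streams <- list()
  for (role in c("parent", "child")) {
    for (sid in c("A", "B")) {
      rec <- if (sid == "A") recA else recB
      idt <- if (sid == "A") idA else idB
      st <- role_stream(rec$skeletons, idt, role)
      if (!is.null(st)) {
        rj <- run_stage("reject",
          reject_inconsistent(st, manifest$seats[[role]],
                              max_jump = config$max_jump,
                              jump_dt = config$jump_dt,
                              shoulder_range = config$shoulder_range,
                              seat_radius = config$seat_radius))
        st <- rj$stream
        if (nrow(rj$log))
          rejections[[paste(sid, role)]] <-
            cbind(sensor = sid, role = role, rj$log)
      }
      streams[[paste0(role, "_", sid)]] <- st
    }
  }
  rejections <- if (length(rejections)) do.call(rbind, rejections) else
    data.frame(sensor = character(), role = character(),
               time = numeric(), rule = character())

  span_end <- max(0, min(unlist(lapply(streams, function(s)
    if (is.null(s) || !length(s$time)) NA else max(s$time)), use.names = FALSE),
    na.rm = TRUE))
  clock <- run_stage("fuse", make_clock(0, span_end, config$clock_rate))
  fused <- list()
  for (role in c("parent", "child"))
    fused[[role]] <- run_stage("fuse",
      fuse_streams(streams[[paste0(role, "_A")]], streams[[paste0(role, "_B")]],
                   clock, facing = if (role == "parent") "A" else "B",
                   max_gap = config$max_gap,
                   max_disagreement = config$max_disagreement))
  dyad <- dyad_series(clock, fused$parent, fused$child, config$clock_rate)
  dyad <- run_stage("smooth", smooth_dyad(dyad, config$smooth_window))

  phases <- run_stage("segment", segment_phases(manifest, span_end))

  # ---- kinematic features
  flatten_y <- function(m) { if (config$planar) m[, 2] <- 0; m }
  feats <- list()
  for (role in c("parent", "child")) {
    feats[[paste0("distance_to_table_", role)]] <-
      distance_to_table(flatten_y(shoulder_center(dyad, role)), clock,
                        scope = role,
                        name = paste0("distance_to_table_", role))
    feats[[paste0("closest_hand_to_table_", role)]] <-
      closest_hand_to_table(dyad, role)
    feats[[paste0("shoulder_orientation_", role)]] <-
      shoulder_orientation(dyad, role)
  }
  hd <- hand_distances(dyad)
  feats$hand_distance_parentL_childR <- hd$parentL_childR
  feats$hand_distance_parentR_childL <- hd$parentR_childL
  feats$relative_shoulder_orientation <- relative_shoulder_orientation(dyad)
  hp <- role_joint(dyad, "parent", "head")
  hc <- role_joint(dyad, "child", "head")
  head_dist <- sqrt(rowSums((hp - hc)^2))
  feats$head_distance <- feature_series("head_distance", clock, head_dist,
                                        !is.finite(head_dist), "dyad", "m")
  hand_speed <- function(role) {
    sl <- track_speed(role_joint(dyad, role, "hand_left"), clock)
    sr <- track_speed(role_joint(dyad, role, "hand_right"), clock)
    v <- rowMeans(cbind(sl$values, sr$values), na.rm = TRUE)
    v[!is.finite(v)] <- NA_real_
    feature_series(paste0("hand_speed_", role), clock, v, !is.finite(v),
                   role, "m/s")
  }
  sp_p <- hand_speed("parent"); sp_c <- hand_speed("child")
  feats$hand_speed_parent <- sp_p
  feats$hand_speed_child <- sp_c
  contrib <- movement_contribution(sp_p, sp_c, config$contribution_window)
  feats$movement_contribution_parent <- contrib$parent
  feats$movement_contribution_child <- contrib$child

  events <- run_stage("events",
    count_hand_contacts(hd, config$contact_threshold,
                        config$contact_hysteresis, config$contact_debounce))

  # ---- audio: VAD + attribution on the reference sensor (A)
  audio <- run_stage("audio", {
    act <- vad(recA$audio$samples, recA$audio$rate,
               frame = config$vad_frame, hop = config$vad_hop,
               audio_start = recA$audio_start)
    az <- resample_to_clock(recA$source_angle$time, recA$source_angle$azimuth,
                            act$time, max_gap = 0.1)
    heads_p <- resample_to_clock(clock, hp, act$time, config$max_gap)$values
    heads_c <- resample_to_clock(clock, hc, act$time, config$max_gap)$values
    W_A <- invert_transform(calA$transform)
    attr_to <- attribute_source(az$values, heads_p, heads_c, W_A,
                                config$azimuth_tolerance, config$azimuth_margin)
    attr_to[!act$active] <- "silence"
    act$azimuth <- az$values
    act$attributed_to <- attr_to
    act
  })
  utterances <- run_stage("audio", sound_activity_by_participant(audio))
  turns <- count_speech_turns(utterances)

  # ---- per-phase summary (single source of truth for the report)
  rows <- list()
  for (i in seq_len(nrow(phases))) {
    for (f in feats) {
      s <- summarize_feature(f, phases[i, ])
      rows[[length(rows) + 1L]] <- data.frame(
        phase = phases$name[i], feature = f$name, scope = f$scope,
        units = f$units, mean = s$mean, min = s$min, max = s$max,
        gap_fraction = s$gap_fraction, n = s$n)
    }
  }
  summary <- do.call(rbind, rows)

  results <- list(calibration = list(A = calA, B = calB), sync = sync,
                  identity = list(A = idA, B = idB),
                  rejections = rejections, dyad = dyad, phases = phases,
                  features = feats, events = events, audio = audio,
                  utterances = utterances, speech_turns = turns,
                  summary = summary, config = config)
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

# CSV/YAML outputs for a pipeline run.
write_results <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dy <- results$dyad
  long <- do.call(rbind, lapply(c("parent", "child"), function(role)
    do.call(rbind, lapply(joint_ids(), function(j) {
      p <- joint_slab(dy[[role]]$pos, j)
      data.frame(time = dy$clock, role = role, joint = j,
                 x = p[, 1], y = p[, 2], z = p[, 3],
                 gap = dy[[role]]$gap[, j],
                 provenance = dy[[role]]$provenance[, j])
    }))))
  utils::write.csv(long, file.path(out_dir, "dyad_series.csv"), row.names = FALSE)
  fl <- do.call(rbind, lapply(results$features, function(f)
    data.frame(time = f$time, feature = f$name, scope = f$scope,
               value = f$values, gap = f$gap)))
  utils::write.csv(fl, file.path(out_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(results$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(results$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(results$utterances, file.path(out_dir, "utterances.csv"),
                   row.names = FALSE)
  utils::write.csv(results$audio, file.path(out_dir, "audio_activity.csv"),
                   row.names = FALSE)
  utils::write.csv(results$rejections, file.path(out_dir, "rejections.log"),
                   row.names = FALSE)
  calA <- results$calibration$A
  yaml::write_yaml(list(
    rotation = as.list(as.numeric(t(calA$transform$rotation))),
    translation = as.list(calA$transform$translation),
    rmse = calA$rmse, offset = results$sync$offset),
    file.path(out_dir, "calibration_result.yaml"), precision = 12L)
  invisible(out_dir)
}

#' Render a figure-style report for a pipeline run
#'
#' One PNG with the session's time-series panels: distances, shoulder
#' orientation (45 and 90 degree reference lines), relative orientation,
#' movement contribution with the head-distance overlay, and the
#' per-participant sound-activity raster. Gaps render as blanks; parent
#' green, child blue. All printed numbers come from the precomputed
#' summary, never recomputed.
#'
#' @param results a [run_pipeline()] result.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_report <- function(results, path) {
  if (is.null(results$features) || length(results$features) == 0L)
    abort_dyadscope("EmptyReport", "no features to report")
  f <- results$features
  pg <- "#2e7d32"; cb <- "#1565c0"
  grDevices::png(path, width = 1100, height = 1500)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(5, 1), mar = c(3.5, 4, 2.5, 1))
  on.exit(graphics::par(old), add = TRUE)
  plot_two <- function(fp, fc, main, ylab, ref = NULL, ref_col = NULL) {
    rng <- range(c(fp$values, fc$values, ref), na.rm = TRUE)
    plot(fp$time, fp$values, type = "l", col = pg, ylim = rng,
         xlab = "time (s)", ylab = ylab, main = main)
    graphics::lines(fc$time, fc$values, col = cb)
    if (!is.null(ref))
      graphics::abline(h = ref, col = ref_col, lty = 2)
    for (b in results$phases$start[-1]) graphics::abline(v = b, col = "grey70")
  }
  plot_two(f$distance_to_table_parent, f$distance_to_table_child,
           "Shoulder-center distance to the table center", "m")
  plot_two(f$shoulder_orientation_parent, f$shoulder_orientation_child,
           "Shoulder orientation", "deg", ref = c(45, 90),
           ref_col = c("red", "purple"))
  plot(f$relative_shoulder_orientation$time,
       f$relative_shoulder_orientation$values, type = "l", col = "black",
       xlab = "time (s)", ylab = "deg", main = "Relative shoulder orientation")
  graphics::abline(h = c(0, 45, 90), col = c("red", "green", "purple"), lty = 2)
  cc <- f$movement_contribution_child$values
  plot(f$movement_contribution_child$time, cc, type = "h", col = cb,
       ylim = c(0, 1), xlab = "time (s)", ylab = "child share",
       main = "Contribution to movement (bars) and head distance (red)")
  ok <- is.finite(f$head_distance$values)
  if (any(ok)) {
    hd <- f$head_distance$values
    graphics::lines(f$head_distance$time, hd / max(hd, na.rm = TRUE),
                    col = "red")
  }
  ut <- results$utterances
  plot(NULL, xlim = range(results$dyad$clock), ylim = c(0, 3), yaxt = "n",
       xlab = "time (s)", ylab = "", main = "Sound activity by participant")
  graphics::axis(2, at = c(1, 2), labels = c("child", "parent"), las = 2)
  if (nrow(ut) == 0L) {
    graphics::text(mean(range(results$dyad$clock)), 1.5,
                   "no attributed activity")
  } else {
    y <- ifelse(ut$speaker == "parent", 2, 1)
    graphics::rect(ut$start, y - 0.3, ut$end, y + 0.3,
                   col = ifelse(ut$speaker == "parent", pg, cb), border = NA)
  }
  invisible(path)
}
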