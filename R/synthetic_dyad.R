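# Synthetic two-sensor dyad recordings with full ground truth.
#
# The generator states a world and emits exactly what the acquisition
# application would have saved from it: seated parent and child torsos at
# 90 degrees around the table, mean-reverting (Ornstein-Uhlenbeck)
# positional jitter, attention-driven torso rotations, scripted hand
# contacts and speech bursts, two sensors with an unknown proper rigid
# transform and clock offset, a shared clap, frame drops and a scripted
# child-off-camera hole. Every hidden quantity is returned as ground
# truth so each pipeline stage can be checked end to end.

#' Default session geometry
#'
#' Table center at the world origin; parent seat at (0.6, 0, 0.6) m and
#' child seat at (0.6, 0, -0.6) m, i.e. seat directions 90 degrees apart
#' as seen from the table. The z axis (chessboard column direction) is
#' chosen so a torso facing the table center reads a 45 degree shoulder
#' orientation and one facing the partner's spot reads 90 degrees. Phase
#' plan: free interactive play 240 s, directed game 120 s, free play with
#' the parent occupied 120 s.
#'
#' @return a [session_manifest()].
#' @export
default_geometry <- function() {
  session_manifest(
    phases = data.frame(
      name = c("free_play", "directed_game", "parent_occupied"),
      duration = c(240, 120, 120)),
    seats = list(parent = c(0.6, 0, 0.6), child = c(0.6, 0, -0.6)),
    participants = list(parent = list(role = "parent"),
                        child = list(role = "child")))
}

#' Construct a dyad behavioural profile
#'
#' All the knobs the generator turns: per-participant mean shoulder-center
#' distance to the table, jitter levels, attention-target mixture and
#' dwell time, the expected child share of movement, the speech schedule
#' and the scripted hand-contact count.
#'
#' @param name profile name.
#' @param parent_dist,child_dist mean shoulder-center-to-table distances (m).
#' @param dist_sd stationary sd of the mean-reverting distance jitter (m).
#' @param hand_sd stationary sd of the hand jitter (m).
#' @param tau jitter mean-reversion time (s).
#' @param leadership expected child share of movement, in \[0, 1\].
#' @param attention_parent,attention_child named numeric
#'   (`table`/`partner`/`away`) mixture weights.
#' @param dwell_parent,dwell_child mean attention dwell times (s).
#' @param speech `"alternating"` (dialog-like strict alternation) or
#'   `"sparse_parent"` (child monologue with `parent_bursts` interjections).
#' @param parent_bursts number of parent bursts under `sparse_parent`.
#' @param contacts scripted hand-contact count.
#' @param frame_drop per-frame drop probability.
#' @param sensor_noise_sd per-coordinate sensor noise (m).
#' @param glitch_rate probability of a teleported (inconsistent) frame.
#' @param child_absence length of the scripted child-off-camera hole (s).
#' @return object of class `dyad_profile`.
#' @export
dyad_profile <- function(name = "custom", parent_dist = 0.5, child_dist = 0.4,
                         dist_sd = 0.03, hand_sd = 0.032, tau = 2,
                         leadership = 0.5,
                         attention_parent = c(table = 0.5, partner = 0.3, away = 0.2),
                         attention_child = c(table = 0.6, partner = 0.25, away = 0.15),
                         dwell_parent = 4, dwell_child = 4,
                         speech = "alternating", parent_bursts = 2,
                         contacts = 25, frame_drop = 0.05,
                         sensor_noise_sd = 0.005, glitch_rate = 0.003,
                         child_absence = 10) {
  if (parent_dist <= 0 || child_dist <= 0)
    abort_dyadscope("ProfileError", "mean distances must be > 0")
  if (leadership < 0 || leadership > 1)
    abort_dyadscope("ProfileError", "leadership ratio must lie in [0, 1]")
  if (contacts < 0)
    abort_dyadscope("ProfileError", "contact count must be >= 0")
  structure(as.list(environment()), class = "dyad_profile")
}

#' Control dyad profile
#'
#' Parent close to the table (mean 0.50 m), balanced movement leadership,
#' dialog-like alternating speech and 25 scripted hand contacts.
#' @return a [dyad_profile()].
#' @export
profile_control <- function() {
  dyad_profile(name = "control", parent_dist = 0.50, child_dist = 0.40,
               leadership = 0.5, speech = "alternating", contacts = 25)
}

#' Pathological dyad profile
#'
#' Withdrawn, near-static parent far from the table (mean 0.80 m), child
#' leading ~90% of the movement, sparse parent speech yielding four speech
#' turns, and 20 scripted hand contacts.
#' @return a [dyad_profile()].
#' @export
profile_pathological <- function() {
  dyad_profile(name = "pathological", parent_dist = 0.80, child_dist = 0.40,
               leadership = 0.9, dist_sd = 0.03,
               attention_parent = c(table = 0.8, partner = 0.05, away = 0.15),
               dwell_parent = 15,
               speech = "sparse_parent", parent_bursts = 2, contacts = 20)
}

# Stationary Ornstein-Uhlenbeck sample path via its AR(1) discretisation.
ou_path <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
  innov[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(innov, a, method = "recursive"))
}

# Piecewise-constant attention target sequence over n ticks.
attention_targets <- function(n, dt, weights, dwell_mean) {
  weights <- weights / sum(weights)
  out <- character(0)
  while (length(out) < n) {
    tgt <- sample(names(weights), 1L, prob = weights)
    len <- max(1L, as.integer(round(stats::rexp(1, 1 / dwell_mean) / dt)))
    out <- c(out, rep(tgt, len))
  }
  out[seq_len(n)]
}

unit_h <- function(v) { v[2] <- 0; v / sqrt(sum(v^2)) }

# Smooth each column with a short centered moving average (torso turns are
# not instantaneous).
smooth_cols <- function(m, k) {
  half <- k %/% 2L
  apply(m, 2, function(x) roll_sum(x, half) / roll_sum(rep(1, length(x)), half))
}

# True world-frame joint tracks for one participant over ticks tw.
participant_tracks <- function(tw, seat, partner_seat, dist_mean, half_width,
                               head_up, hand_radius, profile, move_scale,
                               attention, dwell) {
  n <- length(tw)
  dt <- tw[2] - tw[1]
  u <- unit_h(seat)                                # seat direction
  w <- c(u[3], 0, -u[1])                           # lateral (horizontal)
  d <- dist_mean + ou_path(n, dt, profile$dist_sd * move_scale, profile$tau)
  lat <- ou_path(n, dt, profile$dist_sd * 2 / 3 * move_scale, profile$tau)
  hgt <- ou_path(n, dt, profile$dist_sd / 3, profile$tau)
  sc <- cbind(d * u[1] + lat * w[1], hgt, d * u[3] + lat * w[3])
  tgt <- attention_targets(n, dt, attention, dwell)
  bench <- c(-1.5, 0, 0)                           # psychologist's bench
  face <- matrix(NA_real_, n, 3)
  for (lab in unique(tgt)) {
    rows <- tgt == lab
    aim <- switch(lab,
                  table = matrix(0, sum(rows), 3),
                  partner = matrix(partner_seat, sum(rows), 3, byrow = TRUE),
                  away = matrix(bench, sum(rows), 3, byrow = TRUE))
    face[rows, ] <- aim - sc[rows, , drop = FALSE]
  }
  face[, 2] <- 0
  face <- face / sqrt(rowSums(face^2))
  face <- smooth_cols(face, max(3L, as.integer(0.5 / dt)))
  face <- face / sqrt(rowSums(face^2))
  sdir <- cbind(face[, 3], 0, -face[, 1])          # shoulder line direction
  sl <- sc + half_width * sdir
  sr <- sc - half_width * sdir
  head <- sc + matrix(c(0, head_up, 0), n, 3, byrow = TRUE)
  # hands rest near the table edge on this participant's side
  sc_dir <- cbind(sc[, 1], 0, sc[, 3])
  sc_dir <- sc_dir / sqrt(rowSums(sc_dir^2))
  hand_jit <- function() cbind(ou_path(n, dt, profile$hand_sd * move_scale, 0.7),
                               ou_path(n, dt, profile$hand_sd * move_scale * 0.5, 0.7),
                               ou_path(n, dt, profile$hand_sd * move_scale, 0.7))
  hl <- hand_radius * sc_dir + 0.10 * sdir + hand_jit()
  hr <- hand_radius * sc_dir - 0.10 * sdir + hand_jit()
  hl[, 2] <- hl[, 2] - 0.05
  hr[, 2] <- hr[, 2] - 0.05
  list(shoulder_center = sc, shoulder_left = sl, shoulder_right = sr,
       head = head, hand_left = hl, hand_right = hr, face = face)
}

# Raised-cosine blend of the initiating hand toward the target hand's
# (jittering) track during one contact event, so the reach lands on the
# partner's hand wherever it actually is.
apply_contact <- function(hand, target, tw, start, end, ramp = 0.3) {
  sel <- which(tw >= start - ramp & tw <= end + ramp)
  if (length(sel) == 0L) return(hand)
  tt <- tw[sel]
  alpha <- rep(1, length(sel))
  alpha[tt < start] <- 0.5 * (1 - cos(pi * (tt[tt < start] - (start - ramp)) / ramp))
  alpha[tt > end] <- 0.5 * (1 + cos(pi * (tt[tt > end] - end) / ramp))
  hand[sel, ] <- (1 - alpha) * hand[sel, , drop = FALSE] +
    alpha * target[sel, , drop = FALSE]
  hand
}

# Assemble the 10-joint position array from torso/hand tracks.
assemble_joints <- function(tr) {
  n <- nrow(tr$shoulder_center)
  pos <- array(NA_real_, c(n, 10L, 3L),
               dimnames = list(NULL, joint_ids(), c("x", "y", "z")))
  pos[, "head", ] <- tr$head
  pos[, "shoulder_center", ] <- tr$shoulder_center
  pos[, "shoulder_left", ] <- tr$shoulder_left
  pos[, "shoulder_right", ] <- tr$shoulder_right
  pos[, "hand_left", ] <- tr$hand_left
  pos[, "hand_right", ] <- tr$hand_right
  pos[, "wrist_left", ] <- 0.9 * tr$hand_left + 0.1 * tr$shoulder_left
  pos[, "wrist_right", ] <- 0.9 * tr$hand_right + 0.1 * tr$shoulder_right
  pos[, "elbow_left", ] <- 0.5 * tr$hand_left + 0.5 * tr$shoulder_left
  pos[, "elbow_right", ] <- 0.5 * tr$hand_right + 0.5 * tr$shoulder_right
  pos
}

# Sensor pose: placed across the table from `seat`, optical axis aimed at
# the seat with a small random yaw error and downward pitch.
sensor_pose <- function(seat, distance = 1.0, height = 0.35) {
  u <- unit_h(seat)
  pos <- -distance * u + c(0, height, 0)
  yaw <- stats::runif(1, -3, 3) * pi / 180
  cy <- cos(yaw); sy <- sin(yaw)
  f <- c(cy * u[1] + sy * u[3], 0, -sy * u[1] + cy * u[3])
  pitch <- stats::runif(1, 5, 10) * pi / 180
  f <- c(f[1] * cos(pitch), -sin(pitch), f[3] * cos(pitch))
  f <- f / sqrt(sum(f^2))
  l <- c(f[3], 0, -f[1]) # horizontal left = cross((0,1,0), f), renormalised
  l <- l / sqrt(sum(l^2))
  up <- c(f[2] * l[3] - f[3] * l[2],
          f[3] * l[1] - f[1] * l[3],
          f[1] * l[2] - f[2] * l[1])
  R <- cbind(l, up, f)
  rigid_transform(R, pos)               # sensor -> world
}

# One short speech burst: amplitude-modulated tone + noise.
speech_burst <- function(n, rate, f0) {
  t <- seq_len(n) / rate
  env <- sin(pi * seq_len(n) / n)^2
  0.15 * env * (0.6 * sin(2 * pi * f0 * t) + 0.4 * stats::rnorm(n, 0, 0.5))
}

# Scripted speech schedule: data.frame(speaker, start, end) in world time.
# Nobody speaks a seat-anchored utterance while the child is off-seat.
speech_schedule <- function(profile, duration, hole = c(NA, NA)) {
  slots <- list()
  t <- 2
  while (t < duration - 3) {
    dur <- stats::runif(1, 0.8, 1.3)
    if (is.na(hole[1]) || t + dur < hole[1] - 0.5 || t > hole[2] + 0.5)
      slots[[length(slots) + 1L]] <- c(t, t + dur)
    t <- t + dur + stats::runif(1, 0.6, 1.1)
  }
  if (length(slots) == 0L)
    return(data.frame(speaker = character(), start = numeric(),
                      end = numeric()))
  m <- do.call(rbind, slots)
  n <- nrow(m)
  if (identical(profile$speech, "alternating")) {
    speaker <- rep(c("parent", "child"), length.out = n)
  } else {
    speaker <- rep("child", n)
    k <- profile$parent_bursts
    if (k > 0) {
      at <- round(seq_len(k) * n / (k + 1))
      speaker[at] <- "parent"
    }
  }
  data.frame(speaker = speaker, start = m[, 1], end = m[, 2])
}

#' Generate a complete synthetic recording bundle
#'
#' Synthesises true joint tracks from a [dyad_profile()], projects them
#' into two sensor frames via a random proper rigid transform per sensor,
#' applies random clock offsets (inter-sensor offset in \[0.2, 3\] s),
#' inserts a shared clap into both audio tracks, scripts speech bursts
#' (with matching source-angle samples) and hand contacts, drops frames at
#' the profile's rate plus a scripted child-off-camera hole, and returns a
#' bundle identical in shape to [read_bundle()] output, with ground truth.
#'
#' @param profile a [dyad_profile()].
#' @param duration world recording length after the clap (s).
#' @param seed RNG seed; the same seed reproduces the bundle byte for byte.
#' @param path optional directory; when given the bundle is also written
#'   via [write_bundle()].
#' @param rate skeleton clock rate (Hz, default 30).
#' @param audio_rate audio sample rate (Hz, default 16000).
#' @return list with `recordings` (A, B), `manifest`, `ground_truth`.
#' @export
generate_recording <- function(profile, duration = 240, seed = 1,
                               path = NULL, rate = 30, audio_rate = 16000) {
  if (!inherits(profile, "dyad_profile"))
    abort_dyadscope("ProfileError", "profile must be a dyad_profile")
  if (duration <= 0)
    abort_dyadscope("ProfileError", "duration must be > 0")
  set.seed(seed)
  manifest <- default_geometry()
  pre <- 2                                   # lead-in before the clap
  dt <- 1 / rate
  tw <- seq(-pre, duration, by = dt)
  n <- length(tw)
  seats <- manifest$seats

  m_child <- 2 * profile$leadership
  m_parent <- 2 * (1 - profile$leadership)
  par_tr <- participant_tracks(tw, seats$parent, seats$child,
                               profile$parent_dist, 0.17, 0.25, 0.35,
                               profile, m_parent,
                               profile$attention_parent, profile$dwell_parent)
  chi_tr <- participant_tracks(tw, seats$child, seats$parent,
                               profile$child_dist, 0.12, 0.18, 0.30,
                               profile, m_child,
                               profile$attention_child, profile$dwell_child)

  # scripted child-off-camera hole (the child leaves the chair)
  hole <- c(NA_real_, NA_real_)
  if (profile$child_absence > 0)
    hole <- 0.55 * duration + c(0, profile$child_absence)

  # scripted hand contacts inside the free-play phase, dodging the hole
  contacts <- data.frame(start = numeric(), end = numeric(),
                         mx = numeric(), my = numeric(), mz = numeric())
  if (profile$contacts > 0) {
    span <- c(10, min(duration, manifest$phases$duration[1]) - 10)
    if (span[2] <= span[1])
      abort_dyadscope("ProfileError",
        "recording too short for the scripted contact count")
    pad <- 2                        # clearance around the hole
    hole_lo <- max(span[1], min(span[2], hole[1] - pad))
    hole_len <- if (is.na(hole[1])) 0 else
      max(0, min(span[2], hole[2] + pad) - hole_lo)
    at <- seq(span[1], span[2] - hole_len,
              length.out = profile$contacts) +
      stats::runif(profile$contacts, -0.8, 0.8)
    if (hole_len > 0) at[at >= hole_lo] <- at[at >= hole_lo] + hole_len
    # each contact is initiated by one partner reaching to the other's
    # resting hand; the initiator is the child with the leadership odds
    contacts <- data.frame(start = at, end = at + 0.6,
                           initiator = ifelse(
                             stats::runif(profile$contacts) < profile$leadership,
                             "child", "parent"))
  }
  for (i in seq_len(nrow(contacts))) {
    if (contacts$initiator[i] == "child") {
      chi_tr$hand_left <- apply_contact(chi_tr$hand_left, par_tr$hand_right,
                                        tw, contacts$start[i], contacts$end[i])
    } else {
      par_tr$hand_right <- apply_contact(par_tr$hand_right, chi_tr$hand_left,
                                         tw, contacts$start[i], contacts$end[i])
    }
  }

  pos_parent <- assemble_joints(par_tr)
  pos_child <- assemble_joints(chi_tr)

  # sensor poses, clocks
  T_A <- sensor_pose(seats$parent)           # sensor A -> world (faces parent)
  T_B <- sensor_pose(seats$child)
  W_A <- invert_transform(T_A)
  W_B <- invert_transform(T_B)
  off_A <- pre + stats::runif(1, 0.5, 1.5)
  off_B <- off_A + stats::runif(1, 0.2, 3)

  speech <- speech_schedule(profile, duration, hole)

  recordings <- list()
  slot_roles <- list()
  for (sid in c("A", "B")) {
    off <- if (sid == "A") off_A else off_B
    W <- if (sid == "A") W_A else W_B
    # ---- skeletons: two slots, random role order per sensor
    roles <- sample(c("parent", "child"))
    slot_roles[[sid]] <- roles
    skels <- list()
    for (k in 1:2) {
      role <- roles[k]
      pos_true <- if (role == "parent") pos_parent else pos_child
      keep <- stats::runif(n) >= profile$frame_drop
      if (role == "child" && profile$child_absence > 0)
        keep <- keep & !(tw >= hole[1] & tw < hole[2])
      idx <- which(keep)
      ft <- tw[idx] + off                     # sensor clock
      p <- pos_true[idx, , , drop = FALSE]
      if (profile$sensor_noise_sd > 0) {
        # depth-sensor joint jitter is temporally correlated, not white
        noise <- array(0, c(n, 10L, 3L))
        for (j in 1:10) for (kk in 1:3)
          noise[, j, kk] <- ou_path(n, dt, profile$sensor_noise_sd, 0.6)
        p <- p + noise[idx, , , drop = FALSE]
      }
      if (profile$glitch_rate > 0) {
        gl <- which(stats::runif(length(idx)) < profile$glitch_rate)
        for (g in gl) {
          shift <- stats::rnorm(3, 0, 0.2) + sample(c(-1, 1), 3, TRUE) * 0.8
          p[g, , ] <- sweep(p[g, , , drop = FALSE][1, , ], 2, -shift)
        }
      }
      # into the sensor frame
      flat <- matrix(p, ncol = 3)
      flat <- apply_transform(W, flat)
      p <- array(flat, dim(p))
      skels[[k]] <- skeleton_stream(ft, p, slot = k - 1L)
    }
    # ---- audio
    n_samp <- as.integer(round((duration + off) * audio_rate))
    audio <- stats::rnorm(n_samp, 0, 8e-4)
    clap_i <- as.integer(round(off * audio_rate))
    clap_n <- as.integer(0.025 * audio_rate)
    audio[clap_i:(clap_i + clap_n - 1L)] <-
      0.9 * exp(-seq(0, 6, length.out = clap_n)) *
      sign(stats::rnorm(clap_n))
    for (i in seq_len(nrow(speech))) {
      s0 <- as.integer(round((speech$start[i] + off) * audio_rate))
      nb <- as.integer(round((speech$end[i] - speech$start[i]) * audio_rate))
      f0 <- if (speech$speaker[i] == "parent") 190 else 320
      audio[s0:(s0 + nb - 1L)] <- audio[s0:(s0 + nb - 1L)] +
        speech_burst(nb, audio_rate, f0)
    }
    audio <- pmax(-1, pmin(1, audio))
    # ---- source-angle stream during speech bursts
    ang <- list()
    for (i in seq_len(nrow(speech))) {
      ts <- seq(speech$start[i], speech$end[i], by = 1 / 15)
      head_tr <- if (speech$speaker[i] == "parent") par_tr$head else chi_tr$head
      ti <- pmin(pmax(round((ts + pre) / dt) + 1L, 1L), n)
      az <- point_azimuth(head_tr[ti, , drop = FALSE], W) +
        stats::rnorm(length(ts), 0, 1.5)
      ang[[i]] <- data.frame(time = ts + off, azimuth = az)
    }
    ang <- if (length(ang)) do.call(rbind, ang) else
      data.frame(time = numeric(), azimuth = numeric())
    # ---- calibration corners
    grid_w <- chessboard_grid(3, 4, 0.1)
    corners <- apply_transform(W, as.matrix(grid_w)) +
      matrix(stats::rnorm(12 * 3, 0, 0.001), 12, 3)
    recordings[[sid]] <- sensor_recording(
      sensor_id = sid, skeletons = skels,
      audio = list(samples = audio, rate = audio_rate),
      source_angle = ang,
      calibration = list(points = corners, rows = 3, cols = 4, spacing = 0.1),
      image_timestamps = tw + off,
      audio_start = 0)
  }

  turns <- count_speech_turns(speech)
  gt <- list(
    seed = seed, duration = duration, rate = rate, pre_roll = pre,
    clock_offset_A = off_A, clock_offset_B = off_B,
    offset_B_minus_A = off_B - off_A,
    clap_world_time = 0,
    sensor_A_to_world = as.list(c(t(T_A$rotation), T_A$translation)),
    sensor_B_to_world = as.list(c(t(T_B$rotation), T_B$translation)),
    contacts = lapply(seq_len(nrow(contacts)), function(i)
      list(start = contacts$start[i], end = contacts$end[i],
           initiator = contacts$initiator[i])),
    n_contacts = nrow(contacts),
    utterances = lapply(seq_len(nrow(speech)), function(i)
      list(speaker = speech$speaker[i], start = speech$start[i],
           end = speech$end[i])),
    n_speech_turns = turns,
    leadership = profile$leadership,
    profile = profile$name,
    slot_roles = slot_roles,
    child_absence_start = 0.55 * duration,
    child_absence = profile$child_absence)
  gt$tracks <- data.frame(
    time = tw,
    parent_sc_dist = sqrt(rowSums(par_tr$shoulder_center^2)),
    child_sc_dist = sqrt(rowSums(chi_tr$shoulder_center^2)))
  # full truth arrays kept in memory only (too large for the yaml sidecar)
  gt$pos_parent <- pos_parent
  gt$pos_child <- pos_child
  gt$world_ticks <- tw

  bundle <- list(recordings = recordings, manifest = manifest,
                 ground_truth = gt)
  if (!is.null(path)) {
    gt_disk <- gt
    gt_disk$pos_parent <- NULL; gt_disk$pos_child <- NULL
    gt_disk$world_ticks <- NULL
    write_bundle(recordings, manifest, path, ground_truth = gt_disk)
  }
  bundle
}
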