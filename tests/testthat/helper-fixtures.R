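# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except what a test itself writes to tempdir().

# A constant 10-joint pose centered at `base` with plausible limb offsets.
const_pose <- function(base = c(0.4, 0, 0.4), shoulder_dir = c(1, 0, 0),
                       half_width = 0.17) {
  sc <- base
  sl <- sc + half_width * shoulder_dir
  sr <- sc - half_width * shoulder_dir
  hl <- sc * 0.5 + c(0, -0.05, 0) + 0.1 * shoulder_dir
  hr <- sc * 0.5 + c(0, -0.05, 0) - 0.1 * shoulder_dir
  pose <- rbind(head = sc + c(0, 0.25, 0), shoulder_center = sc,
                shoulder_left = sl, shoulder_right = sr,
                elbow_left = (sl + hl) / 2, elbow_right = (sr + hr) / 2,
                wrist_left = 0.9 * hl + 0.1 * sl,
                wrist_right = 0.9 * hr + 0.1 * sr,
                hand_left = hl, hand_right = hr)
  unname(pose[joint_ids(), ])
}

# Stream of n frames, all at `pose` (or per-frame poses via `pose_fn(i)`).
const_stream <- function(n, pose = const_pose(), t0 = 0, rate = 30,
                         slot = 0L, pose_fn = NULL) {
  pos <- array(NA_real_, c(n, 10L, 3L))
  for (i in seq_len(n))
    pos[i, , ] <- if (is.null(pose_fn)) pose else pose_fn(i)
  skeleton_stream(t0 + (seq_len(n) - 1) / rate, pos, slot = slot)
}

# Minimal dyad series with both participants at constant poses.
const_dyad <- function(n = 30, parent_pose = const_pose(c(0.35, 0, 0.35)),
                       child_pose = const_pose(c(0.3, 0, -0.3), half_width = 0.12),
                       rate = 30) {
  clock <- make_clock(0, (n - 1) / rate, rate)
  mk <- function(pose) {
    pos <- array(rep(pose, each = n), c(n, 10L, 3L),
                 dimnames = list(NULL, joint_ids(), c("x", "y", "z")))
    list(pos = pos, gap = matrix(FALSE, n, 10L),
         provenance = matrix("A", n, 10L))
  }
  dyad_series(clock, mk(parent_pose), mk(child_pose), rate)
}

# Small fast profile for end-to-end tests (no scripted sparse events that
# need a long session).
quick_profile <- function(...) {
  args <- list(...)
  base <- list(name = "quick", contacts = 0, child_absence = 0,
               frame_drop = 0.02, glitch_rate = 0)
  do.call(dyad_profile, utils::modifyList(base, args))
}

run_pipeline_quiet <- function(...) suppressWarnings(run_pipeline(...))

# Dyad with prescribed shoulder-line directions (unit, world frame).
orient_pair <- function(parent_dir, child_dir = c(1, 0, 0)) {
  dy <- const_dyad(3)
  for (i in 1:3) {
    dy$parent$pos[i, 3, ] <- 0.17 * parent_dir   # shoulder_left
    dy$parent$pos[i, 4, ] <- -0.17 * parent_dir  # shoulder_right
    dy$child$pos[i, 3, ] <- 0.12 * child_dir
    dy$child$pos[i, 4, ] <- -0.12 * child_dir
  }
  dy
}

# Random proper rotation matrix.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotation_angle_deg <- function(R1, R2) {
  c_ang <- (sum(diag(crossprod(R1, R2))) - 1) / 2
  acos(pmin(1, pmax(-1, c_ang))) * 180 / pi
}
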