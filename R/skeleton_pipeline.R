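# Skeleton stream cleaning and fusion: label each tracked skeleton as
# parent or child by seat proximity, suppress inconsistent skeletons,
# merge the two calibrated clock-aligned sensor streams into one
# gap-explicit dyad series on a common 30 Hz clock, and smooth.

#' Construct a dyad series
#'
#' The fused, world-frame, common-clock representation of both
#' participants' joint tracks. Gaps are explicit (`gap` mask true iff the
#' position is undefined) and every retained sample is provenance-tagged
#' with the sensor it came from; nothing is ever interpolated or imputed.
#'
#' @param clock uniform tick times (seconds, world clock).
#' @param parent,child per-role lists with `pos` (`T x 10 x 3`), `gap`
#'   (`T x 10` logical) and `provenance` (`T x 10` character, "A"/"B"/NA).
#' @param rate clock rate (Hz).
#' @return object of class `dyad_series`.
#' @export
dyad_series <- function(clock, parent, child, rate = 30) {
  for (side in list(parent, child)) {
    stopifnot(dim(side$pos)[1] == length(clock),
              identical(dim(side$gap), dim(side$pos)[1:2]))
    if (any(is.na(side$pos[, , 1]) != side$gap))
      abort_dyadscope("ParseError", "gap mask must mirror undefined positions")
  }
  structure(list(clock = clock, rate = rate, parent = parent, child = child),
            class = "dyad_series")
}

#' @export
print.dyad_series <- function(x, ...) {
  gp <- mean(x$parent$gap); gc <- mean(x$child$gap)
  cat(sprintf("<dyad_series> %d ticks @ %g Hz, gap fraction parent %.1f%% child %.1f%%\n",
              length(x$clock), x$rate, 100 * gp, 100 * gc))
  invisible(x)
}

# Horizontal (x, z) distance between points and a seat position.
horizontal_distance <- function(xyz, seat) {
  sqrt((xyz[, 1] - seat[1])^2 + (xyz[, 3] - seat[3])^2)
}

# n x 3 slice of one joint's positions (robust to n == 1 dimension drop
# and to arrays without dimnames).
joint_slab <- function(pos, joint) {
  if (is.character(joint)) joint <- match(joint, joint_ids())
  matrix(pos[, joint, ], ncol = 3L)
}

#' Assign parent/child identity to tracked person slots
#'
#' Each sensor-local slot is labelled, per 1 s window, with the role whose
#' seat is nearest to the slot's median shoulder-center (horizontal
#' distance). Confidence is the margin between the two seat distances
#' normalised by the seat separation. When both slots of a sensor claim
#' the same seat for more than `max_conflict` seconds, the farther slot's
#' frames are flagged (`AmbiguousIdentity` warning) and left unassigned.
#'
#' @param skeletons list of world-frame [skeleton_stream()]s for one sensor.
#' @param seats named list `parent`/`child` of world seat positions.
#' @param window window length in seconds (default 1).
#' @param max_conflict tolerated conflict run length in seconds (default 2).
#' @return data.frame with sensor-slot, window start/end, role, confidence.
#' @export
assign_identity <- function(skeletons, seats, window = 1, max_conflict = 2) {
  sep <- sqrt(sum((seats$parent - seats$child)[c(1, 3)]^2))
  per_slot <- lapply(skeletons, function(st) {
    if (length(st$time) == 0L)
      return(NULL)
    bin <- floor(st$time / window)
    sc <- (st$pos[, "shoulder_left", , drop = FALSE] +
           st$pos[, "shoulder_right", , drop = FALSE]) / 2
    sc <- matrix(sc, ncol = 3)
    ub <- sort(unique(bin))
    med <- t(vapply(ub, function(b) {
      rows <- which(bin == b & !is.na(sc[, 1]))
      if (length(rows) == 0L) return(c(NA_real_, NA_real_, NA_real_))
      apply(sc[rows, , drop = FALSE], 2, stats::median)
    }, numeric(3)))
    dp <- horizontal_distance(med, seats$parent)
    dc <- horizontal_distance(med, seats$child)
    data.frame(slot = st$slot, start = ub * window, end = (ub + 1) * window,
               role = ifelse(is.na(dp), NA,
                             ifelse(dp <= dc, "parent", "child")),
               distance = pmin(dp, dc),
               confidence = pmin(1, abs(dp - dc) / sep))
  })
  out <- do.call(rbind, per_slot)
  if (is.null(out) || nrow(out) == 0L) return(out)
  # resolve seat conflicts between slots window by window: nearest slot wins
  if (length(unique(out$slot)) > 1L) {
    key <- paste(out$start, out$role)
    dup <- key[!is.na(out$role)][duplicated(key[!is.na(out$role)])]
    conflict <- !is.na(out$role) & key %in% dup
    if (any(conflict)) {
      for (k in unique(key[conflict])) {
        rows <- which(key == k & conflict)
        loser <- rows[-which.min(out$distance[rows])]
        out$role[loser] <- NA
        out$confidence[loser] <- 0
      }
      runs <- rle(conflict[order(out$start)])
      if (max(runs$lengths[runs$values]) * window > max_conflict)
        warn_dyadscope("AmbiguousIdentity",
          "both slots claimed the same seat for longer than the tolerated run; frames left unassigned")
    }
  }
  out$distance <- NULL
  out
}

# Per-frame role labels for a stream, from an assign_identity() table.
frame_roles <- function(stream, assignment) {
  rows <- assignment[assignment$slot == stream$slot, , drop = FALSE]
  if (nrow(rows) == 0L) return(rep(NA_character_, length(stream$time)))
  idx <- findInterval(stream$time, rows$start)
  role <- rep(NA_character_, length(stream$time))
  ok <- idx >= 1L & stream$time < rows$end[pmax(idx, 1L)]
  role[ok] <- rows$role[idx[ok]]
  role
}

#' Suppress inconsistent skeleton frames
#'
#' A frame is dropped when any of three rules fires: (a) a joint moves more
#' than `max_jump` meters from its value in the previous kept frame within
#' less than `jump_dt` seconds; (b) the shoulder-to-shoulder distance falls
#' outside `shoulder_range`; (c) the shoulder center lies more than
#' `seat_radius` meters (horizontally) from the assigned seat. Thresholds
#' come from seated adult/child anthropometry and are all configurable.
#'
#' @param stream a [skeleton_stream()] in the world frame.
#' @param seat assigned world seat position (3-vector), or `NULL` to skip
#'   rule (c).
#' @param max_jump,jump_dt,shoulder_range,seat_radius rule thresholds.
#' @return list with `stream` (kept frames) and `log` (data.frame of
#'   dropped frame times and the rule that fired).
#' @export
reject_inconsistent <- function(stream, seat = NULL, max_jump = 0.5,
                                jump_dt = 0.1, shoulder_range = c(0.15, 0.75),
                                seat_radius = 1.5) {
  n <- length(stream$time)
  if (n == 0L) return(list(stream = stream, log = data.frame(time = numeric(),
                                                             rule = character())))
  sl <- joint_slab(stream$pos, "shoulder_left")
  sr <- joint_slab(stream$pos, "shoulder_right")
  sw <- sqrt(rowSums((sl - sr)^2))
  bad_b <- !is.na(sw) & (sw < shoulder_range[1] | sw > shoulder_range[2])
  bad_c <- rep(FALSE, n)
  if (!is.null(seat)) {
    sc <- (sl + sr) / 2
    bad_c <- !is.na(sc[, 1]) & horizontal_distance(sc, seat) > seat_radius
  }
  keep <- logical(n)
  rule <- rep(NA_character_, n)
  last_pos <- NULL; last_t <- -Inf
  for (i in seq_len(n)) {
    if (bad_b[i]) { rule[i] <- "shoulder_width"; next }
    if (bad_c[i]) { rule[i] <- "seat_radius"; next }
    p <- stream$pos[i, , ]
    if (!is.null(last_pos) && (stream$time[i] - last_t) < jump_dt) {
      d <- sqrt(rowSums((p - last_pos)^2))
      if (any(d > max_jump, na.rm = TRUE)) { rule[i] <- "jump"; next }
    }
    keep[i] <- TRUE
    last_pos <- p; last_t <- stream$time[i]
  }
  dropped <- which(!keep)
  kept <- skeleton_stream(stream$time[keep],
                          stream$pos[keep, , , drop = FALSE],
                          stream$state[keep, , drop = FALSE], stream$slot)
  list(stream = kept,
       log = data.frame(time = stream$time[dropped], rule = rule[dropped]))
}

# Resample one stream's joints onto the clock; joint-level gaps where the
# joint is missing in the source frame or no frame is near enough.
stream_on_clock <- function(stream, clock, max_gap = 0.05) {
  rs <- resample_to_clock(stream$time, stream$pos, clock, max_gap)
  gap <- is.na(rs$values[, , 1])
  list(pos = rs$values, gap = gap)
}

#' Fuse two sensors' streams for one participant
#'
#' Per clock tick and joint: when both sensors contribute a sample within
#' `max_gap`, the facing sensor's value is taken provided the sensors
#' disagree by at most `max_disagreement` meters (otherwise the tick is a
#' gap and the disagreement is logged); when only one contributes, its
#' value is taken; when neither does, the tick is a gap. Fusion therefore
#' never invents coordinates.
#'
#' @param streamA,streamB world-frame, clock-aligned [skeleton_stream()]s
#'   for the same participant (either may be `NULL`).
#' @param clock uniform world clock.
#' @param facing which sensor faces this participant ("A" faces the parent,
#'   "B" the child).
#' @param max_gap resampling gap tolerance (s).
#' @param max_disagreement sensor disagreement tolerance (m).
#' @return list with `pos`, `gap`, `provenance`, and `disagreements`
#'   (data.frame of tick, joint, distance).
#' @export
fuse_streams <- function(streamA, streamB, clock, facing = "A",
                         max_gap = 0.05, max_disagreement = 0.10) {
  Tn <- length(clock)
  empty <- list(pos = array(NA_real_, c(Tn, 10L, 3L)),
                gap = matrix(TRUE, Tn, 10L))
  a <- if (is.null(streamA) || length(streamA$time) == 0L) empty
       else stream_on_clock(streamA, clock, max_gap)
  b <- if (is.null(streamB) || length(streamB$time) == 0L) empty
       else stream_on_clock(streamB, clock, max_gap)
  pos <- array(NA_real_, c(Tn, 10L, 3L),
               dimnames = list(NULL, joint_ids(), c("x", "y", "z")))
  prov <- matrix(NA_character_, Tn, 10L, dimnames = list(NULL, joint_ids()))
  both <- !a$gap & !b$gap
  onlyA <- !a$gap & b$gap
  onlyB <- a$gap & !b$gap
  d2 <- (a$pos[, , 1] - b$pos[, , 1])^2 + (a$pos[, , 2] - b$pos[, , 2])^2 +
        (a$pos[, , 3] - b$pos[, , 3])^2
  agree <- both & d2 <= max_disagreement^2
  conflict <- both & d2 > max_disagreement^2
  useA <- onlyA | (agree & facing == "A")
  useB <- onlyB | (agree & facing == "B")
  for (k in 1:3) {
    slab <- pos[, , k]
    slab[useA] <- a$pos[, , k][useA]
    slab[useB] <- b$pos[, , k][useB]
    pos[, , k] <- slab
  }
  prov[useA] <- "A"; prov[useB] <- "B"
  gap <- is.na(pos[, , 1])
  idx <- which(conflict, arr.ind = TRUE)
  list(pos = pos, gap = gap, provenance = prov,
       disagreements = data.frame(tick = idx[, 1],
                                  joint = joint_ids()[idx[, 2]],
                                  distance = sqrt(d2[conflict])))
}

# Centered rolling sum with edge-shrinking windows (vectorised).
roll_sum <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L); hi <- pmin(i + half, n)
  cs[hi + 1L] - cs[lo]
}

#' Smooth a dyad series with a gap-aware moving average
#'
#' Per joint coordinate, a centered moving average over the non-gap samples
#' inside the window; gaps remain gaps and contribute nothing. Window 1 is
#' the identity.
#'
#' @param series a [dyad_series()].
#' @param window odd window length in frames (default 5).
#' @return smoothed [dyad_series()].
#' @export
smooth_dyad <- function(series, window = 5) {
  if (window %% 2 == 0 || window < 1)
    abort_dyadscope("InvalidWindow", "smoothing window must be odd and >= 1")
  if (window == 1) return(series)
  half <- (window - 1L) %/% 2L
  for (role in c("parent", "child")) {
    side <- series[[role]]
    for (j in seq_len(10L)) {
      m <- as.numeric(!side$gap[, j])
      cnt <- roll_sum(m, half)
      for (k in 1:3) {
        v <- side$pos[, j, k]
        v[is.na(v)] <- 0
        sm <- roll_sum(v, half) / pmax(cnt, 1)
        sm[side$gap[, j]] <- NA_real_
        series[[role]]$pos[, j, k] <- sm
      }
    }
  }
  series
}

#' Segment the session into the protocol phases
#'
#' Lays the manifest's phase plan as consecutive half-open segments
#' `[start, end)` from world time 0, truncating at the recording end.
#' Phases falling entirely beyond the recording are dropped with a warning.
#'
#' @param manifest a [session_manifest()].
#' @param span_end recording end (seconds, world clock).
#' @return data.frame with `name`, `start`, `end`.
#' @export
segment_phases <- function(manifest, span_end) {
  plan <- manifest$phases
  if (nrow(plan) == 0L)
    abort_dyadscope("EmptySegment", "phase plan is empty")
  bounds <- c(0, cumsum(plan$duration))
  start <- bounds[-length(bounds)]
  end <- pmin(bounds[-1], span_end)
  keep <- start < span_end
  if (!all(keep) || any(end[keep] < bounds[-1][keep]))
    warning("recording shorter than the phase plan; truncating")
  out <- data.frame(name = plan$name[keep], start = start[keep], end = end[keep])
  if (nrow(out) == 0L)
    abort_dyadscope("EmptySegment", "recording does not cover any phase")
  out
}
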