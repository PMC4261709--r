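# Kinematic feature suite on a fused dyad series: proximity to the table,
# inter-hand distances, torso (shoulder-line) orientation, movement speed
# and per-partner contribution to movement, approach/avoid labelling,
# debounced hand-contact events, and per-phase summaries. All features
# propagate gaps; none imputes.

#' Construct a feature series
#'
#' @param name feature name.
#' @param time clock tick times.
#' @param values numeric values (meters, degrees, or dimensionless ratio).
#' @param gap logical gap mask (`TRUE` where the feature is undefined).
#' @param scope `"parent"`, `"child"` or `"dyad"`.
#' @param units unit string.
#' @return object of class `feature_series`.
#' @export
feature_series <- function(name, time, values, gap = !is.finite(values),
                           scope = "dyad", units = "") {
  stopifnot(length(time) == length(values), length(gap) == length(values))
  values[gap] <- NA_real_
  structure(list(name = name, time = time, values = values, gap = gap,
                 scope = scope, units = units),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s [%s, %s]: %d ticks, %.1f%% gaps, mean %.3f\n",
              x$name, x$scope, x$units, length(x$time), 100 * mean(x$gap),
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

# n x 3 track of one joint for one role; NA rows are gaps.
role_joint <- function(dyad, role, joint) joint_slab(dyad[[role]]$pos, joint)

#' Shoulder center of a participant
#'
#' The geometric midpoint of the left and right shoulder joints; a gap
#' wherever either shoulder is missing.
#'
#' @param dyad a [dyad_series()].
#' @param role `"parent"` or `"child"`.
#' @return `T x 3` matrix (NA rows are gaps).
#' @export
shoulder_center <- function(dyad, role) {
  (role_joint(dyad, role, "shoulder_left") +
   role_joint(dyad, role, "shoulder_right")) / 2
}

#' Distance from a point track to the table center
#'
#' Per tick 3D Euclidean distance between the track and the table center
#' (the world origin by calibration convention).
#'
#' @param track `T x 3` matrix.
#' @param time clock times.
#' @param table_center 3-vector (default the origin).
#' @param scope,name passed to [feature_series()].
#' @return a [feature_series()] in meters.
#' @export
distance_to_table <- function(track, time, table_center = c(0, 0, 0),
                              scope = "dyad", name = "distance_to_table") {
  d <- sqrt((track[, 1] - table_center[1])^2 + (track[, 2] - table_center[2])^2 +
            (track[, 3] - table_center[3])^2)
  feature_series(name, time, d, gap = !is.finite(d), scope = scope, units = "m")
}

#' Cross-pair hand distances of the dyad
#'
#' The two distances between the partners' opposed hands: parent's left
#' hand to child's right hand, and parent's right hand to child's left
#' hand (the pairs that face each other across the table).
#'
#' @param dyad a [dyad_series()].
#' @return list of two [feature_series()] (`parentL_childR`,
#'   `parentR_childL`), meters.
#' @export
hand_distances <- function(dyad) {
  pl <- role_joint(dyad, "parent", "hand_left")
  pr <- role_joint(dyad, "parent", "hand_right")
  cl <- role_joint(dyad, "child", "hand_left")
  cr <- role_joint(dyad, "child", "hand_right")
  d1 <- sqrt(rowSums((pl - cr)^2))
  d2 <- sqrt(rowSums((pr - cl)^2))
  list(parentL_childR = feature_series("hand_distance_parentL_childR",
                                       dyad$clock, d1, !is.finite(d1),
                                       "dyad", "m"),
       parentR_childL = feature_series("hand_distance_parentR_childL",
                                       dyad$clock, d2, !is.finite(d2),
                                       "dyad", "m"))
}

#' Distance from a participant's closest hand to the table center
#'
#' Per tick minimum over the participant's two hands of the distance to
#' the table center; if one hand is a gap the other is used, and the tick
#' is a gap only when both hands are.
#'
#' @param dyad a [dyad_series()].
#' @param role `"parent"` or `"child"`.
#' @param table_center 3-vector.
#' @return a [feature_series()] in meters.
#' @export
closest_hand_to_table <- function(dyad, role, table_center = c(0, 0, 0)) {
  hl <- role_joint(dyad, role, "hand_left")
  hr <- role_joint(dyad, role, "hand_right")
  dl <- sqrt(colSums((t(hl) - table_center)^2))
  dr <- sqrt(colSums((t(hr) - table_center)^2))
  d <- pmin(dl, dr, na.rm = TRUE)
  d[!is.finite(dl) & !is.finite(dr)] <- NA_real_
  feature_series(paste0("closest_hand_to_table_", role), dyad$clock, d,
                 !is.finite(d), role, "m")
}

# Acute angle (degrees, [0, 90]) between horizontally projected direction
# vectors and the z axis (u = NULL) or between two such vectors.
acute_horizontal_angle <- function(u, v = NULL, min_len = 0.01) {
  ux <- u[, 1]; uz <- u[, 3]
  ul <- sqrt(ux^2 + uz^2)
  if (is.null(v)) { cosang <- abs(uz) / ul; vl <- 1 }
  else {
    vx <- v[, 1]; vz <- v[, 3]
    vl <- sqrt(vx^2 + vz^2)
    cosang <- abs(ux * vx + uz * vz) / (ul * vl)
  }
  ang <- acos(pmin(1, pmax(0, cosang))) * 180 / pi
  ang[!is.finite(ang) | ul < min_len | vl < min_len] <- NA_real_
  ang
}

#' Shoulder orientation of a participant
#'
#' The acute angle between the horizontally projected shoulder-to-shoulder
#' line and the world z axis (the chessboard column direction). By the
#' seat geometry, a torso facing the table center reads ~45 deg and one
#' facing the partner's spot reads ~90 deg. Ticks whose horizontal
#' shoulder projection is shorter than 1 cm are degenerate and become gaps.
#'
#' @param dyad a [dyad_series()].
#' @param role `"parent"` or `"child"`.
#' @return a [feature_series()] in degrees, values in \[0, 90\].
#' @export
shoulder_orientation <- function(dyad, role) {
  u <- role_joint(dyad, role, "shoulder_left") -
       role_joint(dyad, role, "shoulder_right")
  ang <- acute_horizontal_angle(u)
  feature_series(paste0("shoulder_orientation_", role), dyad$clock, ang,
                 !is.finite(ang), role, "deg")
}

#' Relative shoulder orientation of the dyad
#'
#' The acute angle between the parent's and the child's horizontally
#' projected shoulder lines: ~0 deg when the partners are face to face,
#' oscillating between 45 and 90 deg when both face the table.
#'
#' @param dyad a [dyad_series()].
#' @return a [feature_series()] in degrees, values in \[0, 90\].
#' @export
relative_shoulder_orientation <- function(dyad) {
  up <- role_joint(dyad, "parent", "shoulder_left") -
        role_joint(dyad, "parent", "shoulder_right")
  uc <- role_joint(dyad, "child", "shoulder_left") -
        role_joint(dyad, "child", "shoulder_right")
  ang <- acute_horizontal_angle(up, uc)
  feature_series("relative_shoulder_orientation", dyad$clock, ang,
                 !is.finite(ang), "dyad", "deg")
}

#' Speed of a point track
#'
#' Central-difference speed magnitude on the uniform clock; endpoints use
#' one-sided differences. A gap in the track propagates to the ticks whose
#' difference stencil touches it.
#'
#' @param track `T x 3` matrix.
#' @param time uniform clock times.
#' @param scope,name passed to [feature_series()].
#' @return a [feature_series()] in m/s.
#' @export
track_speed <- function(track, time, scope = "dyad", name = "speed") {
  n <- nrow(track)
  v <- rep(NA_real_, n)
  if (n >= 2) {
    dt <- diff(time)
    if (n > 2) {
      num <- sqrt(rowSums((track[3:n, , drop = FALSE] -
                           track[1:(n - 2), , drop = FALSE])^2))
      v[2:(n - 1)] <- num / (time[3:n] - time[1:(n - 2)])
    }
    v[1] <- sqrt(sum((track[2, ] - track[1, ])^2)) / dt[1]
    v[n] <- sqrt(sum((track[n, ] - track[n - 1, ])^2)) / dt[n - 1]
  }
  v[!is.finite(track[, 1])] <- NA_real_   # a gap tick has no speed either
  feature_series(name, time, v, gap = !is.finite(v), scope = scope,
                 units = "m/s")
}

# Trailing-window mean over non-gap samples (window in ticks).
trailing_mean <- function(x, k) {
  m <- as.numeric(is.finite(x))
  xz <- ifelse(is.finite(x), x, 0)
  cs <- c(0, cumsum(xz)); cm <- c(0, cumsum(m))
  i <- seq_along(x)
  lo <- pmax(i - k + 1L, 1L)
  n_valid <- cm[i + 1L] - cm[lo]
  s <- cs[i + 1L] - cs[lo]
  out <- s / n_valid
  out[n_valid == 0] <- NA_real_
  out
}

#' Per-partner contribution to movement
#'
#' The ratio between one partner's windowed mean speed and the sum of both
#' partners' windowed mean speeds, using a trailing window ("who is moving
#' the most in the previous frames"). Where the summed speed falls below
#' `eps` neither partner is moving and the tick is a gap. Wherever
#' defined, the two contributions sum to exactly 1.
#'
#' @param speed_parent,speed_child speed [feature_series()] on a common
#'   clock.
#' @param window trailing window in seconds (default 1.0).
#' @param eps no-movement floor in m/s (default 1e-3).
#' @return list of two ratio [feature_series()] (`parent`, `child`).
#' @export
movement_contribution <- function(speed_parent, speed_child, window = 1.0,
                                  eps = 1e-3) {
  stopifnot(length(speed_parent$time) == length(speed_child$time), window > 0)
  dt <- if (length(speed_parent$time) > 1) diff(speed_parent$time[1:2]) else 1
  k <- max(1L, as.integer(round(window / dt)))
  vp <- trailing_mean(speed_parent$values, k)
  vc <- trailing_mean(speed_child$values, k)
  tot <- vp + vc
  cc <- vc / tot
  cc[!is.finite(tot) | tot < eps] <- NA_real_
  cp <- 1 - cc
  list(parent = feature_series("movement_contribution_parent",
                               speed_parent$time, cp, !is.finite(cp),
                               "parent", "ratio"),
       child = feature_series("movement_contribution_child",
                              speed_child$time, cc, !is.finite(cc),
                              "child", "ratio"))
}

#' Label a distance series as approaching / moving apart / stable
#'
#' Sign of the windowed derivative of the distance with a dead band:
#' a decreasing distance means the partners approach, an increasing one
#' that they move apart, and derivatives inside `dead_band` are stable.
#'
#' @param distance a distance [feature_series()].
#' @param window derivative window in seconds (default 1.0).
#' @param dead_band dead band in m/s (default 0.01).
#' @return character vector per tick: `"approaching"`, `"moving_apart"`,
#'   `"stable"`, or `NA` in gaps.
#' @export
approach_avoid <- function(distance, window = 1.0, dead_band = 0.01) {
  t <- distance$time
  dt <- if (length(t) > 1) diff(t[1:2]) else 1
  k <- max(1L, as.integer(round(window / dt)))
  x <- distance$values
  n <- length(x)
  deriv <- rep(NA_real_, n)
  lo <- pmax(seq_len(n) - k, 1L)
  deriv <- (x - x[lo]) / (t - t[lo])
  deriv[seq_len(min(k, n))] <- NA_real_
  out <- rep(NA_character_, n)
  out[is.finite(deriv) & deriv < -dead_band] <- "approaching"
  out[is.finite(deriv) & deriv > dead_band] <- "moving_apart"
  out[is.finite(deriv) & abs(deriv) <= dead_band] <- "stable"
  out
}

#' Detect debounced hand-contact events
#'
#' A contact starts when the minimum of the two cross-pair hand distances
#' drops below `threshold` and ends when it rises above
#' `threshold + hysteresis`; events separated by less than `debounce`
#' merge. Gap ticks can neither start nor sustain a contact.
#'
#' @param hands result of [hand_distances()] (or any list of two distance
#'   [feature_series()] on a common clock).
#' @param threshold contact threshold in meters (default 0.10).
#' @param hysteresis release hysteresis in meters (default 0.02).
#' @param debounce merge window in seconds (default 0.25).
#' @return data.frame of events with `start`, `end`, `min_distance`.
#' @export
count_hand_contacts <- function(hands, threshold = 0.10, hysteresis = 0.02,
                                debounce = 0.25) {
  stopifnot(threshold > 0)
  d <- pmin(hands[[1]]$values, hands[[2]]$values, na.rm = TRUE)
  t <- hands[[1]]$time
  in_contact <- FALSE
  events <- list()
  start <- NA_real_; mind <- Inf
  for (i in seq_along(d)) {
    x <- d[i]
    if (!is.finite(x)) x <- Inf
    if (!in_contact && x < threshold) {
      in_contact <- TRUE; start <- t[i]; mind <- x
    } else if (in_contact) {
      mind <- min(mind, x)
      if (x > threshold + hysteresis) {
        events[[length(events) + 1L]] <- c(start, t[i], mind)
        in_contact <- FALSE
      }
    }
  }
  if (in_contact)
    events[[length(events) + 1L]] <- c(start, t[length(t)], mind)
  if (length(events) == 0L)
    return(data.frame(start = numeric(), end = numeric(),
                      min_distance = numeric()))
  ev <- as.data.frame(do.call(rbind, events))
  names(ev) <- c("start", "end", "min_distance")
  # debounce: merge events whose inter-event silence is shorter than debounce
  merged <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    last <- nrow(merged)
    if (ev$start[i] - merged$end[last] < debounce) {
      merged$end[last] <- ev$end[i]
      merged$min_distance[last] <- min(merged$min_distance[last],
                                       ev$min_distance[i])
    } else {
      merged <- rbind(merged, ev[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Summarise a feature over a phase segment
#'
#' @param feature a [feature_series()].
#' @param segment one row of [segment_phases()] (or any list with `start`,
#'   `end`; the segment is half-open `[start, end)`).
#' @return list with `mean`, `min`, `max`, `gap_fraction`, `n`, and
#'   `defined` (`FALSE` when every tick in the segment is a gap).
#' @export
summarize_feature <- function(feature, segment) {
  sel <- feature$time >= segment$start & feature$time < segment$end
  v <- feature$values[sel]
  g <- feature$gap[sel]
  ok <- v[!g]
  if (length(ok) == 0L)
    return(list(mean = NA_real_, min = NA_real_, max = NA_real_,
                gap_fraction = 1, n = sum(sel), defined = FALSE))
  list(mean = mean(ok), min = min(ok), max = max(ok),
       gap_fraction = mean(g), n = sum(sel), defined = TRUE)
}
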