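# Spatial calibration (rigid roto-translation between the two sensors,
# estimated from chessboard-corner correspondences) and temporal
# synchronisation (shared hand clap detected in both audio tracks).

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper orthonormal matrix (`det = +1`; reflections
#'   are rejected).
#' @param translation length-3 numeric vector (meters).
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    abort_dyadscope("DegenerateConfiguration",
                    "rotation must be orthonormal with det = +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.3f, %.3f, %.3f) m\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Estimate the rigid transform between two point sets
#'
#' Least-squares orthogonal Procrustes (Kabsch) solution for the proper
#' rigid transform `R p + t` minimising the summed squared residual between
#' `points_src` mapped into the destination frame and `points_dst`. The
#' determinant of the rotation is constrained to +1, so reflections are
#' never returned.
#'
#' @param points_src,points_dst `n x 3` matrices of corresponding points,
#'   `n >= 3`, not all collinear.
#' @return list with `transform` ([rigid_transform()]) and `rmse` (meters).
#' @export
estimate_rigid_transform <- function(points_src, points_dst) {
  src <- as.matrix(points_src); dst <- as.matrix(points_dst)
  if (any(!is.finite(src)) || any(!is.finite(dst)))
    abort_dyadscope("InvalidPoint", "correspondences contain non-finite coordinates")
  if (nrow(src) != nrow(dst) || ncol(src) != 3L || ncol(dst) != 3L)
    abort_dyadscope("DegenerateConfiguration", "point sets must be equal-count n x 3")
  if (nrow(src) < 3L)
    abort_dyadscope("DegenerateConfiguration", "need at least 3 correspondences")
  cs <- colMeans(src); cd <- colMeans(dst)
  Xc <- sweep(src, 2, cs); Yc <- sweep(dst, 2, cd)
  sv_x <- svd(Xc)$d
  if (sum(sv_x > 1e-10 * max(sv_x, 1e-300)) < 2L)
    abort_dyadscope("DegenerateConfiguration", "correspondences are collinear")
  H <- crossprod(Xc, Yc)            # 3x3 covariance, src -> dst
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cd - as.numeric(R %*% cs)
  resid <- dst - (src %*% t(R) + matrix(t_vec, nrow(src), 3, byrow = TRUE))
  list(transform = rigid_transform(R, t_vec),
       rmse = sqrt(mean(rowSums(resid^2))))
}

#' Apply a rigid transform
#'
#' Maps points, a [skeleton_stream()] (all non-missing joints, states and
#' timestamps untouched) or another transform (composition `T o x`).
#'
#' @param transform a [rigid_transform()].
#' @param x `n x 3` matrix, 3-vector, `skeleton_stream`, or `rigid_transform`.
#' @return transformed object of the same class.
#' @export
apply_transform <- function(transform, x) {
  R <- transform$rotation; tv <- transform$translation
  if (inherits(x, "skeleton_stream")) {
    pos <- x$pos
    for (k in 1:3)
      pos[, , k] <- x$pos[, , 1] * R[k, 1] + x$pos[, , 2] * R[k, 2] +
        x$pos[, , 3] * R[k, 3] + tv[k]
    out <- x
    out$pos <- pos
    dimnames(out$pos) <- dimnames(x$pos)
    return(out)
  }
  if (inherits(x, "rigid_transform"))
    return(rigid_transform(R %*% x$rotation, as.numeric(R %*% x$translation) + tv))
  if (is.null(dim(x))) return(as.numeric(R %*% x) + tv)
  x %*% t(R) + matrix(tv, nrow(x), 3, byrow = TRUE)
}

#' Invert a rigid transform
#' @param transform a [rigid_transform()].
#' @return the inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -as.numeric(Rt %*% transform$translation))
}

#' Canonical chessboard-corner coordinates in the world frame
#'
#' The world frame is anchored to the chessboard laid on the gaming table:
#' origin at the corner-grid centroid (the table center), y up, z along the
#' board's column direction. Corners are ordered row-major, matching the
#' order the acquisition dialect stores them in `calibration.xml`.
#'
#' @param rows,cols corner-grid dimensions.
#' @param spacing square size in meters.
#' @return `rows*cols x 3` matrix.
#' @export
chessboard_grid <- function(rows = 3, cols = 4, spacing = 0.1) {
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cbind(x = (g$row - (rows + 1) / 2) * spacing,
        y = 0,
        z = (g$col - (cols + 1) / 2) * spacing)
}

#' Calibrate one sensor against the table (world) frame
#'
#' @param calibration calibration block of a [sensor_recording()] (ordered
#'   corner coordinates in the sensor frame plus grid dimensions).
#' @return list with `transform` (sensor -> world [rigid_transform()]) and
#'   `rmse` (meters).
#' @export
calibrate_sensor <- function(calibration) {
  if (is.null(calibration) || nrow(calibration$points) < 6L)
    abort_dyadscope("DegenerateConfiguration", "no usable calibration points")
  world <- chessboard_grid(calibration$rows, calibration$cols, calibration$spacing)
  if (nrow(world) != nrow(calibration$points))
    abort_dyadscope("DegenerateConfiguration",
                    "corner count does not match the declared grid")
  estimate_rigid_transform(calibration$points, world)
}

#' Detect the synchronisation clap in an audio track
#'
#' Scans consecutive 10 ms windows and returns the start time of the first
#' window whose RMS exceeds `max(20 x median RMS of the first 500 ms,
#' 0.05)` full-scale — the "powerful sound detected for the first time"
#' that every sensor stamps as its recording origin.
#'
#' @param samples mono waveform in \[-1, 1\].
#' @param rate sample rate (Hz).
#' @param window analysis window in seconds (default 0.010).
#' @param audio_start sensor-clock time of the first sample.
#' @return clap time in seconds on the sensor clock.
#' @export
detect_clap <- function(samples, rate, window = 0.010, audio_start = 0) {
  if (length(samples) == 0L)
    abort_dyadscope("NoClapFound", "empty audio")
  w <- max(1L, as.integer(round(window * rate)))
  nw <- length(samples) %/% w
  if (nw == 0L) abort_dyadscope("NoClapFound", "audio shorter than one window")
  m <- matrix(samples[seq_len(nw * w)], nrow = w)
  rms <- sqrt(colMeans(m^2))
  base_n <- max(1L, min(nw, as.integer(ceiling(0.5 / window))))
  threshold <- max(20 * stats::median(rms[seq_len(base_n)]), 0.05)
  hit <- which(rms > threshold)
  if (length(hit) == 0L)
    abort_dyadscope("NoClapFound", "no window exceeds the clap threshold")
  audio_start + (hit[1] - 1L) * w / rate
}

#' Synchronise the two sensor clocks from the shared clap
#'
#' @param recA,recB the two [sensor_recording()]s.
#' @param window clap analysis window (seconds).
#' @return list with `clap_time_A`, `clap_time_B`, `offset`
#'   (`clap_time_B - clap_time_A`, seconds) and `detection_window`.
#' @export
sync_from_clap <- function(recA, recB, window = 0.010) {
  ca <- detect_clap(recA$audio$samples, recA$audio$rate, window, recA$audio_start)
  cb <- detect_clap(recB$audio$samples, recB$audio$rate, window, recB$audio_start)
  list(clap_time_A = ca, clap_time_B = cb, offset = cb - ca,
       detection_window = window)
}

# Shift every clock-bearing field of a recording by delta seconds.
shift_recording <- function(rec, delta) {
  rec$skeletons <- lapply(rec$skeletons, function(st) {
    st$time <- st$time + delta
    st
  })
  rec$source_angle$time <- rec$source_angle$time + delta
  rec$image_timestamps <- rec$image_timestamps + delta
  rec$audio_start <- rec$audio_start + delta
  rec
}

#' Align sensor B's clock to sensor A's
#'
#' Shifts all of B's timestamps (skeleton, source angle, image, audio
#' origin) by `-offset`, so the two claps coincide and inter-sample
#' intervals are preserved exactly.
#'
#' @param sync result of [sync_from_clap()].
#' @param recB sensor B's [sensor_recording()].
#' @return `recB` on sensor A's clock.
#' @export
align_clocks <- function(sync, recB) {
  if (!is.finite(sync$offset))
    abort_dyadscope("DegenerateConfiguration", "non-finite clock offset")
  shift_recording(recB, -sync$offset)
}
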