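# Voice activity detection, speaker attribution via the source-angle
# stream, utterance segmentation and speech-turn counting.
#
# The VAD is a transparent short-time energy detector: frame log-energy is
# compared against a percentile noise floor and squashed through a
# logistic, rather than wrapping an opaque toolkit, so every threshold is
# visible and testable.

#' Framewise voice activity detection
#'
#' Probability is `plogis((E_dB - floor_dB - lift) / scale)` where `E_dB`
#' is the frame energy in dB, `floor_dB` the 10th percentile of frame
#' energies (the noise floor), `lift` = 10 dB and `scale` = 2 dB. A frame
#' is active when the probability reaches 0.5 (i.e. energy 10 dB above the
#' floor) sustained for at least `min_active` seconds.
#'
#' @param samples mono waveform in \[-1, 1\].
#' @param rate sample rate (Hz).
#' @param frame,hop analysis frame and hop in seconds (defaults 25/10 ms).
#' @param lift,scale logistic placement in dB.
#' @param min_active minimum sustained activity in seconds (default 0.1).
#' @param audio_start clock time of the first sample.
#' @return data.frame with `time` (frame start), `probability`, `active`.
#' @export
vad <- function(samples, rate, frame = 0.025, hop = 0.010, lift = 10,
                scale = 2, min_active = 0.1, audio_start = 0) {
  fl <- as.integer(round(frame * rate))
  hl <- as.integer(round(hop * rate))
  if (length(samples) < fl)
    abort_dyadscope("TooShort", "audio shorter than one analysis frame")
  starts <- seq(1L, length(samples) - fl + 1L, by = hl)
  cs <- c(0, cumsum(samples^2))
  energy <- (cs[starts + fl] - cs[starts]) / fl
  e_db <- 10 * log10(energy + 1e-12)
  floor_db <- stats::quantile(e_db, 0.10, names = FALSE)
  prob <- stats::plogis((e_db - floor_db - lift) / scale)
  raw <- prob >= 0.5
  need <- max(1L, as.integer(ceiling(min_active / hop)))
  active <- raw
  if (need > 1L && length(raw) > 0L) {
    r <- rle(raw)
    r$values <- r$values & r$lengths >= need
    active <- inverse.rle(r)
  }
  data.frame(time = audio_start + (starts - 1L) / rate,
             probability = prob, active = active)
}

#' Azimuth of world points in a sensor's frame
#'
#' Degrees, 0 along the sensor optical axis, positive to the sensor's
#' left. Both the synthetic generator and the attribution step use this
#' same convention, via the calibrated world-to-sensor transform.
#'
#' @param points `n x 3` matrix or 3-vector, world frame.
#' @param world_to_sensor a [rigid_transform()] mapping world coordinates
#'   into the sensor frame (x left, y up, z forward).
#' @return azimuths in degrees.
#' @export
point_azimuth <- function(points, world_to_sensor) {
  if (is.null(dim(points))) points <- matrix(points, 1L, 3L)
  q <- apply_transform(world_to_sensor, points)
  atan2(q[, 1], q[, 3]) * 180 / pi
}

#' Attribute a detected sound source to a participant
#'
#' Compares the measured source azimuth against each participant's head
#' azimuth in the sensor frame; the sound is attributed to the participant
#' minimising the absolute azimuth difference, provided that minimum is at
#' most `tolerance` and beats the other participant by at least `margin`
#' (distinguishing voices from other sounds is imperfect; the margin and
#' an explicit `unattributed` class encode that).
#'
#' @param azimuth measured source azimuth in degrees (sensor convention),
#'   possibly a vector.
#' @param head_parent,head_child head positions (world frame) at the same
#'   ticks: `n x 3` matrices or 3-vectors; NA rows where unavailable.
#' @param world_to_sensor a [rigid_transform()] for the sensor that
#'   measured the azimuth.
#' @param tolerance max acceptable azimuth error (degrees, default 15).
#' @param margin required advantage over the other head (degrees, default 5).
#' @return character vector: `"parent"`, `"child"` or `"unattributed"`.
#' @export
attribute_source <- function(azimuth, head_parent, head_child,
                             world_to_sensor, tolerance = 15, margin = 5) {
  if (is.null(dim(head_parent))) head_parent <- matrix(head_parent, 1L, 3L)
  if (is.null(dim(head_child))) head_child <- matrix(head_child, 1L, 3L)
  azp <- point_azimuth(head_parent, world_to_sensor)
  azc <- point_azimuth(head_child, world_to_sensor)
  dp <- abs(azimuth - azp); dc <- abs(azimuth - azc)
  dp[!is.finite(dp)] <- Inf; dc[!is.finite(dc)] <- Inf
  out <- rep("unattributed", length(azimuth))
  out[dp <= tolerance & dp + margin <= dc] <- "parent"
  out[dc <= tolerance & dc + margin <= dp] <- "child"
  out[!is.finite(azimuth)] <- "unattributed"
  out
}

#' Segment attributed audio activity into utterances
#'
#' Maximal runs of active frames carrying a constant parent/child
#' attribution become utterances; runs shorter than `min_duration` are
#' discarded and within-speaker silences shorter than `bridge` are
#' bridged. Unattributed activity never forms an utterance.
#'
#' @param activity data.frame with `time`, `active`, `attributed_to`
#'   (values `parent`/`child`/`unattributed`/`silence`).
#' @param min_duration minimum utterance length in seconds (default 0.2).
#' @param bridge maximum within-speaker silence to bridge (default 0.15).
#' @return data.frame of utterances: `speaker`, `start`, `end`.
#' @export
sound_activity_by_participant <- function(activity, min_duration = 0.2,
                                          bridge = 0.15) {
  lab <- ifelse(activity$active &
                  activity$attributed_to %in% c("parent", "child"),
                activity$attributed_to, "none")
  n <- length(lab)
  if (n == 0L)
    return(data.frame(speaker = character(), start = numeric(), end = numeric()))
  hop <- if (n > 1) activity$time[2] - activity$time[1] else 0.01
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(speaker = r$values,
                     start = activity$time[starts],
                     end = activity$time[ends] + hop)
  runs <- runs[runs$speaker != "none", , drop = FALSE]
  if (nrow(runs) == 0L)
    return(data.frame(speaker = character(), start = numeric(), end = numeric()))
  merged <- runs[1, , drop = FALSE]
  for (i in seq_len(nrow(runs))[-1]) {
    last <- nrow(merged)
    if (runs$speaker[i] == merged$speaker[last] &&
        runs$start[i] - merged$end[last] < bridge) {
      merged$end[last] <- runs$end[i]
    } else {
      merged <- rbind(merged, runs[i, ])
    }
  }
  merged <- merged[merged$end - merged$start >= min_duration, , drop = FALSE]
  rownames(merged) <- NULL
  merged
}

#' Count speech turns
#'
#' A turn is a change of speaker between consecutive utterances, so strict
#' alternation over n utterances yields n - 1 turns and a single speaker
#' yields none. Merging consecutive same-speaker utterances does not
#' change the count.
#'
#' @param utterances data.frame from [sound_activity_by_participant()],
#'   time-ordered.
#' @return integer turn count.
#' @export
count_speech_turns <- function(utterances) {
  s <- utterances$speaker
  if (length(s) < 2L) return(0L)
  sum(s[-1] != s[-length(s)])
}
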