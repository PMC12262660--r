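# Per-frame kinematics derived from the keypoints.
#
# Roles: key point 1 = snout, 3 = body center (speed reference, least
# affected by tail beat), 8 = caudal tip. Heading is the bearing of the
# center->snout vector; the tail angle is the signed deviation of the
# center->tip vector from the body axis (0 = straight fish).

#' Compute per-frame kinematic series
#'
#' @param track a validated [pose_track()].
#' @return data.frame with one row per frame: `frame`, `time_s`,
#'   `heading_deg` (bearing in (-180, 180]; NaN where center and snout
#'   coincide), `dheading_deg` (wrapped |frame-to-frame change| in
#'   \[0, 180\]; NA at frame 1 and around degenerate frames),
#'   `speed_mm_s` (center displacement x pixel pitch x fps; NA at frame 1)
#'   and `tail_angle_deg` (signed, 0 for a collinear fish).
#' @export
compute_kinematics <- function(track) {
  co <- track$coords
  N <- dim(co)[1]
  dy <- co[, 1, 1] - co[, 3, 1]
  dx <- co[, 1, 2] - co[, 3, 2]
  heading <- bearing_deg(dy, dx)
  heading[dy == 0 & dx == 0] <- NaN
  dheading <- c(NA_real_, abs(wrap180(diff(heading))))
  stp <- sqrt(diff(co[, 3, 1])^2 + diff(co[, 3, 2])^2)
  speed <- c(NA_real_, stp * track$pixel_pitch_um / 1000 * track$fps)
  ty <- co[, 8, 1] - co[, 3, 1]
  tx <- co[, 8, 2] - co[, 3, 2]
  tail <- wrap180(bearing_deg(ty, tx) - heading - 180)
  data.frame(frame = seq_len(N), time_s = (seq_len(N) - 1) / track$fps,
             heading_deg = heading, dheading_deg = dheading,
             speed_mm_s = speed, tail_angle_deg = tail)
}

#' Detect speed-threshold movement bouts
#'
#' A movement bout is a maximal run of frames with speed strictly above
#' `threshold_mm_s` lasting at least `min_frames` frames (defaults: 2 mm/s
#' for at least 5 frames, i.e. 31 ms at 160 fps).
#'
#' @param kin data.frame from [compute_kinematics()].
#' @param threshold_mm_s speed threshold (mm/s).
#' @param min_frames minimum run length in frames.
#' @param fps frame rate used for durations; defaults to the rate implied
#'   by `kin$time_s`.
#' @return data.frame of bouts: `start_frame`, `end_frame` (half-open),
#'   `n_frames`, `duration_s`, `max_speed_mm_s`, `max_dheading_deg`.
#' @export
detect_speed_bouts <- function(kin, threshold_mm_s = 2, min_frames = 5,
                               fps = NULL) {
  fps <- fps %||% 1 / diff(kin$time_s[1:2])
  above <- !is.na(kin$speed_mm_s) & kin$speed_mm_s > threshold_mm_s
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  out <- data.frame(start_frame = starts[keep],
                    end_frame = ends[keep] + 1L,
                    n_frames = r$lengths[keep])
  out$duration_s <- out$n_frames / fps
  if (nrow(out) == 0) {
    out$max_speed_mm_s <- out$max_dheading_deg <- numeric(0)
    return(out)
  }
  out$max_speed_mm_s <- mapply(function(s, e)
    max(kin$speed_mm_s[s:(e - 1)], na.rm = TRUE),
    out$start_frame, out$end_frame)
  out$max_dheading_deg <- mapply(function(s, e)
    suppressWarnings(max(kin$dheading_deg[s:(e - 1)], na.rm = TRUE)),
    out$start_frame, out$end_frame)
  out$max_dheading_deg[!is.finite(out$max_dheading_deg)] <- NA_real_
  out
}

#' Kinematic maxima over a time interval
#'
#' Maxima of |heading change|, speed and |tail angle| over the frames
#' whose time falls in `[start_s, end_s)`; NA frames are ignored. Used for
#' the pre-/stimulus/post-window comparisons around a stimulus.
#'
#' @param kin data.frame from [compute_kinematics()].
#' @param start_s,end_s interval bounds in seconds.
#' @return named numeric: `max_dheading_deg`, `max_speed_mm_s`,
#'   `max_tail_angle_deg`.
#' @export
summarize_interval <- function(kin, start_s, end_s) {
  sel <- kin$time_s >= start_s & kin$time_s < end_s
  if (!any(sel)) stop("interval outside acquisition", call. = FALSE)
  mx <- function(v) {
    v <- v[sel]
    v <- v[is.finite(v)]
    if (length(v)) max(v) else NA_real_
  }
  c(max_dheading_deg = mx(abs(kin$dheading_deg)),
    max_speed_mm_s = mx(kin$speed_mm_s),
    max_tail_angle_deg = mx(abs(kin$tail_angle_deg)))
}
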