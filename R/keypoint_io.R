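#' Construct a pose track
#'
#' A pose track holds one larva's keypoint time series: a numeric array of
#' shape \code{frames x 8 x 2} in \code{(y, x)} pixel coordinates (image
#' convention, y increasing downward), together with the acquisition frame
#' rate, the pixel pitch, the plate format and identifiers. Key point 1 is
#' the snout, key point 3 the body center (swim-bladder region) and key
#' point 8 the caudal tip.
#'
#' @param coords numeric array \code{frames x 8 x 2}, \code{(y, x)} order,
#'   in pixels. NAs are permitted until [validate_track()] is applied.
#' @param fps frames per second (default 160).
#' @param pixel_pitch_um micrometres per pixel (default 37.8).
#' @param plate_format `"P24"` or `"P96"`.
#' @param well_id,acquisition_id identifiers used in file output.
#' @return an object of class `pose_track`.
#' @seealso [validate_track()], [read_pose_csv()], [read_pose_netcdf()]
#' @export
pose_track <- function(coords, fps = 160, pixel_pitch_um = 37.8,
                       plate_format = c("P24", "P96"),
                       well_id = "W01", acquisition_id = "A01") {
  plate_format <- match.arg(plate_format)
  if (!is.array(coords) || length(dim(coords)) != 3L)
    stop("coords must be a frames x 8 x 2 array", call. = FALSE)
  if (dim(coords)[2] != 8L)
    stop("keypoint count != 8 (got ", dim(coords)[2], ")", call. = FALSE)
  if (dim(coords)[3] != 2L)
    stop("coords must have 2 axes (y, x); got ", dim(coords)[3], call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0", call. = FALSE)
  if (!is.numeric(pixel_pitch_um) || pixel_pitch_um <= 0)
    stop("pixel_pitch_um must be > 0", call. = FALSE)
  dimnames(coords) <- list(NULL, NULL, c("y", "x"))
  structure(
    list(coords = coords, fps = fps, pixel_pitch_um = pixel_pitch_um,
         plate_format = plate_format, well_id = well_id,
         acquisition_id = acquisition_id),
    class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat(sprintf("<pose_track> well %s acq %s: %d frames @ %g fps, %s, %.3g um/px\n",
              x$well_id, x$acquisition_id, n_frames(x), x$fps,
              x$plate_format, x$pixel_pitch_um))
  invisible(x)
}

#' Number of frames in a pose track
#' @param track a `pose_track`.
#' @export
n_frames <- function(track) dim(track$coords)[1]

#' Describe a stimulus event
#'
#' @param kind `"tap"` (acoustic, 0.1 s), `"dark_flash"` (light-off, 2 s)
#'   or `"none"`.
#' @param onset_s onset in seconds from acquisition start (default 5).
#' @param duration_s stimulus duration; defaults to 0.1 s for a tap and
#'   2 s for a dark flash.
#' @return an object of class `stimulus_event`.
#' @export
stimulus_event <- function(kind = c("tap", "dark_flash", "none"),
                           onset_s = 5, duration_s = NULL) {
  kind <- match.arg(kind)
  duration_s <- duration_s %||% switch(kind, tap = 0.1, dark_flash = 2, none = 0)
  if (onset_s < 0) stop("onset_s must be >= 0", call. = FALSE)
  structure(list(kind = kind, onset_s = onset_s, duration_s = duration_s),
            class = "stimulus_event")
}

#' Bundle pose tracks into a trial set
#'
#' All tracks of a trial set share frame rate and plate format; tracks are
#' keyed by `well_id/acquisition_id`.
#'
#' @param tracks list of `pose_track` objects.
#' @param stimulus optional [stimulus_event()] shared by all acquisitions.
#' @param replicate_count number of replicate acquisitions per fish
#'   (6 for stimulus assays, 10 for spontaneous recording series).
#' @return an object of class `trial_set`.
#' @export
trial_set <- function(tracks, stimulus = NULL, replicate_count = NULL) {
  if (length(tracks) == 0) stop("empty trial set", call. = FALSE)
  stopifnot(all(vapply(tracks, inherits, logical(1), "pose_track")))
  fps <- unique(vapply(tracks, `[[`, numeric(1), "fps"))
  fmt <- unique(vapply(tracks, `[[`, character(1), "plate_format"))
  if (length(fps) != 1) stop("tracks disagree on fps", call. = FALSE)
  if (length(fmt) != 1) stop("tracks disagree on plate_format", call. = FALSE)
  names(tracks) <- vapply(tracks, function(t)
    paste(t$well_id, t$acquisition_id, sep = "/"), character(1))
  structure(list(tracks = tracks, stimulus = stimulus,
                 replicate_count = replicate_count,
                 fps = fps, plate_format = fmt),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d tracks, %s @ %g fps%s\n",
              length(x$tracks), x$plate_format, x$fps,
              if (!is.null(x$stimulus)) paste0(", stimulus ", x$stimulus$kind) else ""))
  invisible(x)
}

#' Gap-fill or reject a pose track
#'
#' Runs of missing coordinates no longer than `max_gap` frames are linearly
#' interpolated per keypoint and axis (runs touching the track edges are
#' filled with the nearest observed value). A track with any longer gap is
#' rejected: the return value is then a `rejected_track` carrying the
#' reason, which [is_rejected()] detects. Validation is idempotent.
#'
#' @param track a `pose_track`.
#' @param max_gap longest missing run (frames) that may be interpolated.
#' @return the gap-filled `pose_track`, or a `rejected_track`.
#' @export
validate_track <- function(track, max_gap = 5) {
  co <- track$coords
  co[is.nan(co)] <- NA_real_
  for (k in seq_len(dim(co)[2])) {
    for (a in 1:2) {
      v <- co[, k, a]
      na <- is.na(v)
      if (!any(na)) next
      if (all(na))
        return(structure(list(track = track,
                              reason = sprintf("keypoint %d axis %d entirely missing", k, a)),
                         class = "rejected_track"))
      r <- rle(na)
      if (max(r$lengths[r$values]) > max_gap)
        return(structure(list(track = track,
                              reason = sprintf("missing run of %d frames exceeds max_gap=%d (keypoint %d)",
                                               max(r$lengths[r$values]), max_gap, k)),
                         class = "rejected_track"))
      idx <- seq_along(v)
      co[, k, a] <- stats::approx(idx[!na], v[!na], xout = idx, rule = 2)$y
    }
  }
  track$coords <- co
  track
}

#' @rdname validate_track
#' @param x object returned by [validate_track()].
#' @export
is_rejected <- function(x) inherits(x, "rejected_track")

# ---------------------------------------------------------------------------
# CSV I/O (long format: well,frame,keypoint_index,y,x; 1-based indices)

#' Read / write pose tracks as long-format CSV
#'
#' The tabular interchange format is one row per (well, frame, keypoint):
#' columns `well, frame, keypoint_index, y, x`, header required, frame and
#' keypoint indices 1-based and frames contiguous per well. Rows may arrive
#' in any order; they are sorted on read, so `write_pose_csv()` followed by
#' `read_pose_csv()` reproduces coordinates exactly.
#'
#' @param path CSV file path.
#' @param fps,pixel_pitch_um,plate_format,acquisition_id acquisition
#'   metadata (CSV carries coordinates only).
#' @return `read_pose_csv()` returns a [trial_set()]; `write_pose_csv()`
#'   returns `path` invisibly.
#' @export
read_pose_csv <- function(path, fps = 160, pixel_pitch_um = 37.8,
                          plate_format = "P24", acquisition_id = "A01") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path)
  need <- c("well", "frame", "keypoint_index", "y", "x")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("CSV missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  data.table::setorderv(dt, c("well", "frame", "keypoint_index"))
  tracks <- lapply(split(dt, by = "well", sorted = TRUE), function(d) {
    fr <- sort(unique(d$frame))
    if (!identical(fr, seq(min(fr), max(fr))) || min(fr) != 1L)
      stop("non-contiguous frame indices for well ", d$well[1], call. = FALSE)
    nf <- length(fr)
    if (nrow(d) != nf * 8L)
      stop("well ", d$well[1], ": expected 8 keypoints per frame", call. = FALSE)
    co <- array(NA_real_, c(nf, 8, 2))
    co[cbind(d$frame, d$keypoint_index, 1L)] <- d$y
    co[cbind(d$frame, d$keypoint_index, 2L)] <- d$x
    pose_track(co, fps = fps, pixel_pitch_um = pixel_pitch_um,
               plate_format = plate_format, well_id = as.character(d$well[1]),
               acquisition_id = acquisition_id)
  })
  trial_set(unname(tracks))
}

#' @rdname read_pose_csv
#' @param trialset a [trial_set()] (or single `pose_track`).
#' @export
write_pose_csv <- function(trialset, path) {
  if (inherits(trialset, "pose_track")) trialset <- trial_set(list(trialset))
  rows <- lapply(trialset$tracks, function(t) {
    nf <- n_frames(t)
    data.table::data.table(
      well = t$well_id,
      frame = rep(seq_len(nf), each = 8L),
      keypoint_index = rep(1:8, nf),
      y = as.vector(t(t$coords[, , 1])),
      x = as.vector(t(t$coords[, , 2])))
  })
  dt <- data.table::rbindlist(rows)
  data.table::setorderv(dt, c("well", "frame", "keypoint_index"))
  data.table::fwrite(dt, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# NetCDF I/O. Schema (documented in README, stands in for the proprietary
# acquisition export): one variable `<well_id>/keypoints` per well with
# dimensions (time, point, axis), axis order (y, x); global attributes
# fps, pixel_pitch_um, plate_format, acquisition_id.

#' Read / write pose tracks as NetCDF-4
#'
#' @param path NetCDF file.
#' @param well_selector optional character vector of well IDs to load.
#' @return `read_pose_netcdf()` returns a [trial_set()];
#'   `write_pose_netcdf()` returns `path` invisibly.
#' @export
read_pose_netcdf <- function(path, well_selector = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vn <- names(nc$var)
  vn <- vn[grepl("/keypoints$", vn) | vn == "keypoints"]
  if (!length(vn)) stop("no keypoint variable found in ", path, call. = FALSE)
  wells <- sub("/?keypoints$", "", vn)
  wells[wells == ""] <- "W01"
  if (!is.null(well_selector)) {
    keep <- wells %in% well_selector
    if (!any(keep)) stop("no selected wells present", call. = FALSE)
    vn <- vn[keep]; wells <- wells[keep]
  }
  ga <- function(att, default) {
    a <- ncdf4::ncatt_get(nc, 0, att)
    if (a$hasatt) a$value else default
  }
  fps <- ga("fps", 160)
  pitch <- ga("pixel_pitch_um", 37.8)
  fmt <- ga("plate_format", "P24")
  acq <- ga("acquisition_id", "A01")
  tracks <- Map(function(v, w) {
    co <- ncdf4::ncvar_get(nc, v, collapse_degen = FALSE)
    if (length(dim(co)) != 3 || dim(co)[2] != 8L)
      stop("keypoint count != 8 in variable ", v, call. = FALSE)
    pose_track(co, fps = fps, pixel_pitch_um = pitch, plate_format = fmt,
               well_id = w, acquisition_id = acq)
  }, vn, wells)
  trial_set(unname(tracks))
}

#' @rdname read_pose_netcdf
#' @param trialset a [trial_set()] (or single `pose_track`).
#' @export
write_pose_netcdf <- function(trialset, path) {
  if (inherits(trialset, "pose_track")) trialset <- trial_set(list(trialset))
  dpoint <- ncdf4::ncdim_def("point", "index", 1:8)
  daxis <- ncdf4::ncdim_def("axis", "yx", 1:2)
  vars <- lapply(trialset$tracks, function(t) {
    dtime <- ncdf4::ncdim_def(paste0(t$well_id, "_time"), "frame",
                              seq_len(n_frames(t)))
    ncdf4::ncvar_def(paste0(t$well_id, "/keypoints"), "pixel",
                     list(dtime, dpoint, daxis), missval = NaN, prec = "double")
  })
  nc <- ncdf4::nc_create(path, vars, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  for (i in seq_along(trialset$tracks))
    ncdf4::ncvar_put(nc, vars[[i]], trialset$tracks[[i]]$coords)
  t1 <- trialset$tracks[[1]]
  ncdf4::ncatt_put(nc, 0, "fps", t1$fps, prec = "double")
  ncdf4::ncatt_put(nc, 0, "pixel_pitch_um", t1$pixel_pitch_um, prec = "double")
  ncdf4::ncatt_put(nc, 0, "plate_format", t1$plate_format)
  ncdf4::ncatt_put(nc, 0, "acquisition_id", t1$acquisition_id)
  invisible(path)
}

#' Read / write stimulus metadata sidecar (JSON)
#'
#' @param stimulus a [stimulus_event()].
#' @param path JSON file path.
#' @export
write_stimulus_json <- function(stimulus, path) {
  jsonlite::write_json(unclass(stimulus), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_json
#' @export
read_stimulus_json <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_event(s$kind, s$onset_s, s$duration_s)
}
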