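# Window extraction and egocentric alignment.
#
# A behavior window is a W-frame slice (default 40 frames = 250 ms at
# 160 fps) of a pose track. Egocentric alignment applies one rigid
# transform per window -- a rotation about the first frame's body center
# that points the center->snout vector "up" (negative y), followed by a
# translation of that center to the origin -- identically to all W frames,
# so within-frame geometry is preserved exactly and the representation is
# invariant to the fish's position and heading at window onset.

#' Cut a pose track into overlapping behavior windows
#'
#' Follows the N - W window convention: a track of N frames yields
#' `N - W` stride-1 windows (1,600 frames -> 1,560 windows), window i
#' covering frames `[i, i + W - 1]`.
#'
#' @param track a [pose_track()].
#' @param W window length in frames (default 40).
#' @param stride step between window starts (default 1).
#' @return list of `behavior_window` objects (fields `start_frame`,
#'   `coords` W x 8 x 2, `aligned`).
#' @export
make_windows <- function(track, W = 40, stride = 1) {
  N <- n_frames(track)
  if (N <= W) stop("track has ", N, " frames; need more than W = ", W,
                   call. = FALSE)
  starts <- seq.int(1L, N - W, by = stride)
  lapply(starts, function(i)
    structure(list(start_frame = i,
                   coords = track$coords[i:(i + W - 1L), , , drop = FALSE],
                   aligned = FALSE),
              class = "behavior_window"))
}

#' Egocentrically align a behavior window
#'
#' Computes the rigid transform from the window's first frame (rotate
#' about the body center so the center-to-snout vector points up, then
#' translate the center to the origin) and applies it to all W frames.
#' After alignment the first-frame center is at `(0, 0)` and the
#' first-frame snout at `(-d, 0)` where d is the center-snout distance.
#' A window whose first-frame center and snout coincide has no defined
#' heading and is flagged `degenerate` instead of transformed.
#'
#' @param window a `behavior_window` from [make_windows()].
#' @return the aligned window (`aligned = TRUE`).
#' @export
egocentric_align <- function(window) {
  if (isTRUE(window$aligned)) return(window)
  co <- window$coords
  c0 <- co[1, 3, ]                      # first-frame body center (y, x)
  v <- co[1, 1, ] - c0                  # center -> snout
  if (sum(v^2) == 0) {
    window$degenerate <- TRUE
    return(window)
  }
  phi <- -pi / 2 - atan2(v[1], v[2])    # rotate v's (x, y)-plane angle to -90
  cs <- cos(phi); sn <- sin(phi)
  y0 <- co[, , 1] - c0[1]
  x0 <- co[, , 2] - c0[2]
  co[, , 2] <- cs * x0 - sn * y0
  co[, , 1] <- sn * x0 + cs * y0
  window$coords <- co
  window$aligned <- TRUE
  window$degenerate <- FALSE
  window
}

#' Fit / apply the per-dataset coordinate normalizer
#'
#' Normalization is fit once on the (aligned) training windows of a plate
#' format and reused unchanged at inference: every coordinate is divided
#' by the dataset maximum absolute coordinate, then the dataset mean of
#' the scaled coordinates is subtracted.
#'
#' @param windows list of aligned `behavior_window`s, a numeric array, or
#'   a `clip_set` of aligned coordinates.
#' @param plate_format recorded for provenance.
#' @return `fit_normalizer()` returns a `normalizer` (fields `scale`,
#'   `offset`); `apply_normalizer()` the normalized window/array.
#' @export
fit_normalizer <- function(windows, plate_format = NULL) {
  vals <- .coord_pool(windows)
  if (length(vals) == 0) stop("empty dataset", call. = FALSE)
  scale <- max(abs(vals))
  if (scale == 0) stop("cannot normalize: all coordinates are zero (scale = 0)",
                       call. = FALSE)
  structure(list(scale = scale, offset = mean(vals / scale),
                 plate_format = plate_format),
            class = "normalizer")
}

.coord_pool <- function(x) {
  if (is.numeric(x)) return(as.vector(x))
  if (inherits(x, "clip_set")) return(as.vector(x$coords))
  if (inherits(x, "behavior_window")) return(as.vector(x$coords))
  unlist(lapply(x, function(w) as.vector(w$coords)), use.names = FALSE)
}

#' @rdname fit_normalizer
#' @param window a `behavior_window` or numeric array.
#' @param normalizer a fitted `normalizer`.
#' @export
apply_normalizer <- function(window, normalizer) {
  stopifnot(inherits(normalizer, "normalizer"))
  if (is.numeric(window))
    return(window / normalizer$scale - normalizer$offset)
  window$coords <- window$coords / normalizer$scale - normalizer$offset
  window$normalized <- TRUE
  window
}

#' Flatten an aligned window to a feature vector
#'
#' Element order is frame-major and fixed across versions: frame 1's
#' 8 keypoints as (y, x) pairs, then frame 2's, and so on, giving length
#' `W * 16` (640 for W = 40). [unflatten_window()] is the inverse.
#'
#' @param window an aligned `behavior_window`.
#' @return numeric vector of length `W * 16`.
#' @export
flatten_window <- function(window) {
  if (!isTRUE(window$aligned))
    stop("window must be egocentrically aligned before flattening",
         call. = FALSE)
  as.vector(aperm(window$coords, c(3, 2, 1)))
}

#' @rdname flatten_window
#' @param values numeric vector of length `W * 16`.
#' @param W window length in frames.
#' @export
unflatten_window <- function(values, W) {
  stopifnot(length(values) == W * 16)
  aperm(array(values, c(2, 8, W)), c(3, 2, 1))
}

#' Time span of a window
#'
#' @param start_frame 1-based first frame of the window.
#' @param W window length in frames.
#' @param fps frames per second.
#' @return `c(start_s, end_s)`; the span is `W / fps` (250 ms for the
#'   default 40 frames at 160 fps).
#' @export
window_time <- function(start_frame, W, fps) {
  if (fps <= 0) stop("fps must be > 0", call. = FALSE)
  start_s <- (start_frame - 1) / fps
  c(start_s = start_s, end_s = start_s + W / fps)
}

#' Featurize a whole track (vectorized)
#'
#' Equivalent to [make_windows()] + [egocentric_align()] +
#' [flatten_window()] (+ [apply_normalizer()] when a normalizer is given)
#' over all stride-1 windows, computed with vectorized arithmetic. Also
#' returns each window's center path length in mm, the displacement
#' measure used for stationary-cluster flagging during clip mining.
#'
#' @param track a [pose_track()].
#' @param W,stride windowing parameters.
#' @param normalizer optional fitted `normalizer`.
#' @return list with `features` (n x W*16 matrix), `start_frames`,
#'   `path_mm` (length n) and `degenerate` (logical).
#' @export
featurize_track <- function(track, W = 40, stride = 1, normalizer = NULL) {
  A <- track$coords
  N <- dim(A)[1]
  if (N <= W) stop("track has ", N, " frames; need more than W = ", W,
                   call. = FALSE)
  starts <- seq.int(1L, N - W, by = stride)
  n <- length(starts)
  c0y <- A[starts, 3, 1]; c0x <- A[starts, 3, 2]
  vy <- A[starts, 1, 1] - c0y; vx <- A[starts, 1, 2] - c0x
  degen <- (vy == 0 & vx == 0)
  phi <- -pi / 2 - atan2(vy, vx)
  cs <- cos(phi); sn <- sin(phi)
  F <- matrix(0, n, W * 16L)
  for (j in seq_len(W)) {
    rows <- starts + j - 1L
    Y0 <- A[rows, , 1] - c0y
    X0 <- A[rows, , 2] - c0x
    base <- (j - 1L) * 16L
    F[, base + seq(1L, 16L, 2L)] <- sn * X0 + cs * Y0   # y'
    F[, base + seq(2L, 16L, 2L)] <- cs * X0 - sn * Y0   # x'
  }
  if (!is.null(normalizer))
    F <- F / normalizer$scale - normalizer$offset
  # center path length per window (mm), on raw coordinates
  stepmm <- sqrt(diff(A[, 3, 1])^2 + diff(A[, 3, 2])^2) *
    track$pixel_pitch_um / 1000
  cum <- c(0, cumsum(stepmm))
  path_mm <- cum[starts + W - 1L] - cum[starts]
  list(features = F, start_frames = starts, path_mm = path_mm,
       degenerate = degen)
}

#' Featurize a clip set
#'
#' Aligns and flattens every clip of a [make_training_corpus()] output.
#'
#' @param clips a `clip_set`.
#' @param normalizer optional fitted `normalizer`.
#' @return n x W*16 feature matrix (row order = clip order).
#' @export
featurize_clips <- function(clips, normalizer = NULL) {
  n <- dim(clips$coords)[1]
  W <- dim(clips$coords)[2]
  F <- matrix(0, n, W * 16L)
  for (i in seq_len(n)) {
    w <- structure(list(start_frame = 1L,
                        coords = array(clips$coords[i, , , ], c(W, 8, 2)),
                        aligned = FALSE),
                   class = "behavior_window")
    F[i, ] <- flatten_window(egocentric_align(w))
  }
  if (!is.null(normalizer))
    F <- F / normalizer$scale - normalizer$offset
  F
}
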