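# Synthetic larval-zebrafish keypoint trajectories.
#
# The simulator emits the same data structure the acquisition hardware
# would (frames x 8 x 2 keypoint arrays in pixels) for scripted sequences
# of the five motor classes, with per-frame ground-truth labels. Class
# templates are tuned so that the defining kinematic inequalities hold on
# the noiseless trajectory:
#   stationary  center speed < 0.5 mm/s
#   scoot       forward translation, |net heading change| < 20 deg
#   turn        30-90 deg reorientation at low displacement, shortest bouts
#   AsLB        C-start-like: latency < 15 ms, peak speed and per-frame
#               heading change >= 5x a scoot's
#   VsLB        O-bend-like: 150-500 ms latency, largest heading change
# Exact magnitudes are simulator parameters, not claims about real fish.

#' Larva body model
#'
#' Places the 8 key points along the midline by arc-length fraction
#' (0 = snout, 1 = caudal tip).
#'
#' @param body_length_mm total midline length; 5-7 dpf larvae measure about
#'   3.56 mm (24-well optics) to 3.85 mm (96-well optics).
#' @param arc_fractions 8 strictly increasing values in \code{[0, 1]} with
#'   endpoints 0 and 1. The default puts the body center (key point 3)
#'   at 30 percent of the body, the swim-bladder region.
#' @return object of class `body_model`.
#' @export
body_model <- function(body_length_mm = 3.7,
                       arc_fractions = c(0, .12, .30, .45, .60, .75, .88, 1)) {
  stopifnot(length(arc_fractions) == 8, body_length_mm > 0)
  if (arc_fractions[1] != 0 || arc_fractions[8] != 1 ||
      any(diff(arc_fractions) <= 0))
    stop("arc_fractions must be strictly increasing from 0 to 1", call. = FALSE)
  structure(list(body_length_mm = body_length_mm,
                 arc_fractions = arc_fractions),
            class = "body_model")
}

#' Simulation configuration
#'
#' @param plate_format `"P24"` or `"P96"`. Sets the defaults for keypoint
#'   noise (70 / 133 um RMS, matching the measured keypoint placement
#'   error of each optical configuration), well radius and body length.
#' @param fps frames per second (default 160).
#' @param acquisition_s recording length in seconds (10 for stimulus
#'   assays, 60 for spontaneous recordings).
#' @param noise_sigma_um target RMS radial deviation of each simulated
#'   keypoint from the noiseless trajectory, micrometres. Per-axis
#'   Gaussian noise of stationary sd `noise_sigma_um / sqrt(2)` is added
#'   independently to every keypoint coordinate.
#' @param noise_ar1 lag-1 autocorrelation of the keypoint noise (default
#'   0.995). Pose-estimation error is dominated by slowly varying,
#'   pose-dependent bias rather than white jitter -- white noise of this
#'   magnitude would alone read as ~15 mm/s of frame-to-frame speed at
#'   160 fps, incompatible with a usable 2 mm/s bout threshold. The AR(1)
#'   model keeps the stationary RMS equal to `noise_sigma_um` while
#'   frame-to-frame speed noise stays near 1 mm/s. Set 0 for white noise.
#' @param pixel_pitch_um micrometres per pixel (default 37.8).
#' @param well_radius_mm circular well radius; trajectories reflect
#'   specularly at the wall.
#' @param body a [body_model()].
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(plate_format = c("P24", "P96"), fps = 160,
                       acquisition_s = 10, noise_sigma_um = NULL,
                       noise_ar1 = 0.995,
                       pixel_pitch_um = 37.8, well_radius_mm = NULL,
                       body = NULL, seed = NULL) {
  plate_format <- match.arg(plate_format)
  noise_sigma_um <- noise_sigma_um %||%
    switch(plate_format, P24 = 70, P96 = 133)
  well_radius_mm <- well_radius_mm %||%
    switch(plate_format, P24 = 7.8, P96 = 3.2)
  body <- body %||%
    body_model(switch(plate_format, P24 = 3.56, P96 = 3.85))
  stopifnot(fps > 0, acquisition_s > 0, noise_sigma_um >= 0,
            noise_ar1 >= 0, noise_ar1 < 1,
            well_radius_mm > body$body_length_mm / 2)
  structure(list(plate_format = plate_format, fps = fps,
                 acquisition_s = acquisition_s,
                 noise_sigma_um = noise_sigma_um, noise_ar1 = noise_ar1,
                 pixel_pitch_um = pixel_pitch_um,
                 well_radius_mm = well_radius_mm, body = body, seed = seed),
            class = "sim_config")
}

# class kinematic templates: defaults and draw ranges
.class_defaults <- list(
  stationary = list(duration_s = 1.0),
  scoot = list(peak_speed = 8, net_heading = 0, wiggle_deg = 5,
               duration_s = 0.30, latency_s = 0, bend_amp = 25, tbf_hz = 22),
  turn = list(peak_speed = 2.5, total_heading = 60, duration_s = 0.15,
              latency_s = 0, bend_amp = 40, tbf_hz = 15),
  AsLB = list(peak_speed = 50, total_heading = 120, duration_s = 0.20,
              latency_s = 0.008, bend_amp = 120, tbf_hz = 45),
  VsLB = list(peak_speed = 25, total_heading = 150, duration_s = 0.25,
              latency_s = 0.30, bend_amp = 150, tbf_hz = 30))

# random per-bout parameter draws (used when a script omits a parameter)
.draw_params <- function(class) {
  sgn <- sample(c(-1, 1), 1)
  switch(class,
    stationary = list(),
    scoot = list(peak_speed = stats::runif(1, 5, 9),
                 net_heading = stats::runif(1, -12, 12)),
    turn = list(peak_speed = stats::runif(1, 2, 3),
                total_heading = sgn * stats::runif(1, 35, 85)),
    AsLB = list(peak_speed = stats::runif(1, 45, 65),
                total_heading = sgn * stats::runif(1, 100, 130),
                latency_s = stats::runif(1, 0.004, 0.012)),
    VsLB = list(peak_speed = stats::runif(1, 20, 30),
                total_heading = sgn * stats::runif(1, 140, 170),
                latency_s = stats::runif(1, 0.16, 0.45)))
}

#' Script a sequence of behavior segments
#'
#' @param segments list of segments, each a list with `class` (one of
#'   `"stationary"`, `"scoot"`, `"turn"`, `"AsLB"`, `"VsLB"`), `onset_s`,
#'   optional `duration_s` and optional kinematic `params` (entries of
#'   `peak_speed` mm/s, `total_heading`/`net_heading` deg, `latency_s`).
#'   Unspecified parameters are drawn from the class range at simulation
#'   time. Movement occupies `[onset_s + latency, onset_s + latency +
#'   duration_s)`; frames outside any segment are stationary.
#' @param acquisition_s recording length the script must fit in.
#' @return object of class `behavior_script`.
#' @export
behavior_script <- function(segments, acquisition_s = 10) {
  segments <- lapply(segments, function(s) {
    if (is.null(s$class) || !s$class %in% names(.class_defaults))
      stop("unknown behavior class: ", s$class %||% "<missing>", call. = FALSE)
    s$duration_s <- s$duration_s %||% .class_defaults[[s$class]]$duration_s
    s$params <- s$params %||% list()
    if (is.null(s$onset_s) || s$onset_s < 0)
      stop("segment onset_s must be >= 0", call. = FALSE)
    s
  })
  if (length(segments) > 1) {
    on <- vapply(segments, `[[`, numeric(1), "onset_s")
    segments <- segments[order(on)]
  }
  end_last <- 0
  for (s in segments) {
    lat_max <- if (s$class == "VsLB") 0.5 else 0.015
    if (s$onset_s < end_last)
      stop("overlapping segments in script", call. = FALSE)
    end_last <- s$onset_s + lat_max + s$duration_s
    if (end_last > acquisition_s)
      stop("segment exceeds acquisition bounds", call. = FALSE)
  }
  structure(list(segments = segments, acquisition_s = acquisition_s),
            class = "behavior_script")
}

#' Keypoint coordinates of a posed midline
#'
#' Builds the 8 keypoints of a larva at a given center position, heading
#' and bend. The body chain starts at the snout and extends backward
#' (direction `heading + 180` deg); `bend_profile[i]` is the signed angle
#' (deg) added at joint i, so a zero profile gives a straight fish and a
#' profile summing to 180 deg curls the tail until its final segment points
#' along the heading again.
#'
#' @param position `(y, x)` of the body center (key point 3), mm.
#' @param heading_deg bearing of the center-to-snout vector (0 = up,
#'   clockwise positive, image convention).
#' @param bend_profile 7 signed joint angles in degrees.
#' @param body a [body_model()].
#' @return 8 x 2 matrix of `(y, x)` coordinates in mm, snout first.
#' @export
midline_pose <- function(position, heading_deg, bend_profile,
                         body = body_model()) {
  stopifnot(length(bend_profile) == 7, length(position) == 2)
  co <- .midline_chain(matrix(bend_profile, 1), heading_deg, body)
  off <- matrix(c(co$y, co$x), 8, 2)
  sweep(off, 2, off[3, ] - c(position[1], position[2]))
}

# vectorized chain: bend T x 7, heading length-T -> snout-relative offsets
# (lists y, x of T x 8 matrices)
.midline_chain <- function(bend, heading_deg, body) {
  T <- nrow(bend)
  seglen <- body$body_length_mm * diff(body$arc_fractions)
  U <- upper.tri(matrix(0, 7, 7), diag = TRUE)  # cumsum across joints
  cumbend <- bend %*% U
  segdir <- (heading_deg + 180) + cumbend          # T x 7 bearings
  rad <- segdir * pi / 180
  dy <- sweep(-cos(rad), 2, seglen, `*`)
  dx <- sweep(sin(rad), 2, seglen, `*`)
  y <- cbind(0, t(apply(dy, 1, cumsum)))
  x <- cbind(0, t(apply(dx, 1, cumsum)))
  if (T == 1) { y <- matrix(y, 1); x <- matrix(x, 1) }
  list(y = y, x = x)
}

# per-segment frame series. n movement frames; returns list of vectors.
.segment_series <- function(class, n, fps, p) {
  k <- seq_len(n)
  def <- .class_defaults[[class]]
  g <- function(nm) p[[nm]] %||% def[[nm]]
  env_sin2 <- sin(pi * (k - 0.5) / n)^2
  if (class == "scoot") {
    h <- g("net_heading") * k / n + g("wiggle_deg") * sin(2 * pi * k / n)
    speed <- g("peak_speed") * env_sin2
    drive <- g("bend_amp") * env_sin2 * sin(2 * pi * g("tbf_hz") * k / fps)
  } else if (class == "turn") {
    h <- g("total_heading") * (1 - cos(pi * k / n)) / 2
    speed <- g("peak_speed") * env_sin2
    drive <- sign(g("total_heading")) * g("bend_amp") * env_sin2
  } else if (class == "AsLB") {
    q <- max(3, round(0.25 * n))
    h <- g("total_heading") * (1 - cos(pi * pmin(k, q) / q)) / 2
    tp <- 0.03
    tt <- k / fps
    speed <- g("peak_speed") * (tt / tp) * exp(1 - tt / tp)
    drive <- sign(g("total_heading")) * g("bend_amp") *
      exp(-((k - q / 2) / q)^2) +
      0.4 * g("bend_amp") * env_sin2 * sin(2 * pi * g("tbf_hz") * k / fps)
  } else if (class == "VsLB") {
    q <- max(4, round(0.6 * n))
    h <- g("total_heading") * (1 - cos(pi * pmin(k, q) / q)) / 2
    speed <- g("peak_speed") * env_sin2
    drive <- sign(g("total_heading")) * g("bend_amp") *
      exp(-((k - q / 2) / (0.8 * q))^2) +
      0.3 * g("bend_amp") * env_sin2 * sin(2 * pi * g("tbf_hz") * k / fps)
  } else stop("no movement template for class ", class)
  list(dheading = diff(c(0, h)), speed = speed, drive = drive)
}

#' Simulate one pose track from a behavior script
#'
#' Deterministic given `config$seed`. Baseline (outside any scripted
#' segment) is stationary: slow passive drift at 0.1 mm/s with a small
#' tail wobble. Gaussian keypoint noise (see [sim_config()]) is added on
#' top of the noiseless trajectory, which is also returned.
#'
#' @param script a [behavior_script()].
#' @param config a [sim_config()].
#' @return list with `track` (a [pose_track()], pixels), `labels`
#'   (character, per-frame ground truth), `noiseless` (frames x 8 x 2
#'   pixel array before noise) and `script`.
#' @export
simulate_track <- function(script, config = sim_config(),
                           well_id = "W01", acquisition_id = "A01") {
  if (!is.null(config$seed)) set.seed(config$seed)
  fps <- config$fps
  T <- round(config$acquisition_s * fps)
  if (script$acquisition_s > config$acquisition_s + 1e-9)
    stop("script exceeds acquisition bounds", call. = FALSE)
  dt <- 1 / fps

  # baseline: stationary drift + tail wobble
  speed <- rep(0.1, T)
  dhead <- rep(0, T)
  drive <- 2 * sin(2 * pi * 1.5 * seq_len(T) / fps + stats::runif(1, 0, 2 * pi))
  labels <- rep("stationary", T)

  for (s in script$segments) {
    if (s$class == "stationary") next
    p <- utils::modifyList(.draw_params(s$class), s$params)
    lat <- p$latency_s %||% .class_defaults[[s$class]]$latency_s
    i0 <- round((s$onset_s + lat) * fps) + 1L
    n <- max(2L, round(s$duration_s * fps))
    i1 <- min(T, i0 + n - 1L)
    if (i0 > T) next
    ser <- .segment_series(s$class, n, fps, p)
    idx <- i0:i1
    kk <- seq_along(idx)
    speed[idx] <- ser$speed[kk]
    dhead[idx] <- ser$dheading[kk]
    drive[idx] <- ser$drive[kk]
    labels[idx] <- s$class
  }

  heading <- stats::runif(1, -180, 180) + cumsum(dhead)
  step <- bearing_unit(heading) * (speed * dt)
  r0 <- stats::runif(1, 0, 0.5 * config$well_radius_mm)
  a0 <- stats::runif(1, 0, 2 * pi)
  pos <- matrix(c(r0 * cos(a0), r0 * sin(a0)), T, 2, byrow = TRUE) +
    apply(step, 2, cumsum)

  # specular reflection at the well wall (slow path, only when needed)
  rmax <- config$well_radius_mm - 0.6 * config$body$body_length_mm
  if (any(rowSums(pos^2) > rmax^2)) {
    pos[1, ] <- c(r0 * cos(a0), r0 * sin(a0)) + step[1, ]
    for (t in 2:T) {
      cand <- pos[t - 1, ] + step[t, ]
      r <- sqrt(sum(cand^2))
      if (r > rmax) {
        nrm <- cand / r
        v <- bearing_unit(heading[t])[1, ]
        v <- v - 2 * sum(v * nrm) * nrm
        heading[t:T] <- heading[t:T] - heading[t] + bearing_deg(v[1], v[2])
        step[t:T, ] <- bearing_unit(heading[t:T]) * (speed[t:T] * dt)
        cand <- nrm * rmax
      }
      pos[t, ] <- cand
    }
  }

  bend <- outer(drive, c(.05, .1, .2, .35, .55, .8, 1))
  ch <- .midline_chain(bend, heading, config$body)
  # anchor the body center (key point 3) at pos
  y_mm <- (pos[, 1] - ch$y[, 3]) + ch$y
  x_mm <- (pos[, 2] - ch$x[, 3]) + ch$x

  pitch_mm <- config$pixel_pitch_um / 1000
  origin_px <- ceiling(1.2 * config$well_radius_mm / pitch_mm)
  noiseless <- array(0, c(T, 8, 2))
  noiseless[, , 1] <- y_mm / pitch_mm + origin_px
  noiseless[, , 2] <- x_mm / pitch_mm + origin_px
  co <- noiseless
  if (config$noise_sigma_um > 0) {
    sd_px <- config$noise_sigma_um / sqrt(2) / config$pixel_pitch_um
    rho <- config$noise_ar1 %||% 0
    if (rho > 0) {
      # stationary AR(1) per keypoint coordinate, marginal sd = sd_px
      innov <- matrix(stats::rnorm(T * 16L, 0, sd_px * sqrt(1 - rho^2)), T, 16L)
      init <- stats::rnorm(16L, 0, sd_px)
      noise <- vapply(seq_len(16L), function(j)
        as.numeric(stats::filter(innov[, j], rho, "recursive", init = init[j])),
        numeric(T))
      co <- co + array(noise, dim(co))
    } else {
      co <- co + array(stats::rnorm(length(co), 0, sd_px), dim(co))
    }
  }
  track <- pose_track(co, fps = fps, pixel_pitch_um = config$pixel_pitch_um,
                      plate_format = config$plate_format,
                      well_id = well_id, acquisition_id = acquisition_id)
  list(track = track, labels = labels, noiseless = noiseless, script = script)
}

#' Simulate a single stimulus trial
#'
#' A 10 s acquisition with the stimulus delivered at 5.0 s. A responding
#' larva performs the elicited behavior (AsLB for a tap, VsLB for a dark
#' flash) with its class latency; a non-responder keeps its baseline
#' behavior. Baseline scoots are scripted away from the response window.
#'
#' @param kind `"tap"` or `"dark_flash"`.
#' @param respond logical; does this larva respond?
#' @param config a [sim_config()].
#' @return list with `track`, `labels`, `stimulus` and `script`.
#' @export
make_stimulus_trial <- function(kind = c("tap", "dark_flash"), respond = TRUE,
                                config = sim_config(),
                                well_id = "W01", acquisition_id = "A01") {
  kind <- match.arg(kind)
  if (!is.null(config$seed)) set.seed(config$seed)
  segs <- list(
    list(class = "scoot", onset_s = 1.2 + stats::runif(1, 0, 1.2)),
    list(class = "scoot", onset_s = 7.5 + stats::runif(1, 0, 1.2)))
  if (respond)
    segs <- c(segs, list(list(
      class = if (kind == "tap") "AsLB" else "VsLB", onset_s = 5.0)))
  script <- behavior_script(segs, acquisition_s = config$acquisition_s)
  config$seed <- NULL
  sim <- simulate_track(script, config, well_id, acquisition_id)
  sim$stimulus <- stimulus_event(kind, onset_s = 5)
  sim
}

# default corpus sizes per plate format (clips per class)
.default_corpus_counts <- function(plate_format) {
  switch(plate_format,
    P24 = c(stationary = 66, scoot = 102, turn = 75, AsLB = 60, VsLB = 137),
    P96 = c(stationary = 432, movement = 486, AsLB = 170, VsLB = 309))
}

#' Generate a labeled training corpus of 40-frame behavior clips
#'
#' Emits class-conformant keypoint clips for training the classifier. The
#' default class counts are 66/102/75/60/137 clips (stationary, scoot,
#' turn, AsLB, VsLB) for 24-well plates and 432/486/170/309 (stationary,
#' movement, AsLB, VsLB) for 96-well plates. A 96-well `"movement"` clip
#' is a scoot or a turn, drawn at random with equal odds.
#'
#' Clip windows are sampled at varying phase of the bout, as manually
#' reviewed clips would be: for sustained movement classes the window
#' start is drawn uniformly from 16 frames before movement onset to 20
#' frames before movement offset, so the classifier sees early, mid and
#' late bout phases; startle clips (AsLB/VsLB) draw their start from a
#' Gaussian-weighted offset around the bend onset (range -16..+4 frames,
#' sd 6), mimicking stimulus-locked clip mining: most clips are
#' burst-aligned -- a long stationary lead-in before a C-bend is hard to
#' tell from the delayed-onset signature that defines an O-bend -- while
#' the tails keep enough phase variety for frame-level majority voting.
#'
#' @param class_counts named integer vector (class -> clip count) or
#'   `NULL` for the plate-format defaults.
#' @param config a [sim_config()].
#' @param W clip length in frames (default 40).
#' @return object of class `clip_set`: list with `coords`
#'   (n x W x 8 x 2 pixel array), `labels` (factor over the plate's class
#'   set), and acquisition metadata.
#' @export
make_training_corpus <- function(class_counts = NULL, config = sim_config(),
                                 W = 40) {
  if (!is.null(config$seed)) set.seed(config$seed)
  counts <- class_counts %||% .default_corpus_counts(config$plate_format)
  cs <- class_set(config$plate_format)
  bad <- setdiff(names(counts), cs)
  if (length(bad))
    stop("unknown class for plate format ", config$plate_format, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(counts < 1)) stop("class counts must be >= 1", call. = FALSE)
  clip_cfg <- config
  clip_cfg$seed <- NULL
  clip_cfg$acquisition_s <- 1.0
  Tclip <- round(clip_cfg$acquisition_s * config$fps)
  n <- sum(counts)
  coords <- array(NA_real_, c(n, W, 8, 2))
  labels <- character(n)
  i <- 0L
  for (cl in names(counts)) {
    for (j in seq_len(counts[[cl]])) {
      i <- i + 1L
      sim_cl <- cl
      if (cl == "movement") sim_cl <- sample(c("scoot", "turn"), 1)
      segs <- if (sim_cl == "stationary") list() else
        list(list(class = sim_cl, onset_s = 0.1))
      script <- behavior_script(segs, acquisition_s = clip_cfg$acquisition_s)
      sim <- simulate_track(script, clip_cfg,
                            well_id = sprintf("sim%04d", i))
      if (sim_cl == "stationary") {
        onset <- sample(Tclip - W, 1)
      } else {
        mvf <- which(sim$labels != "stationary")
        m0 <- min(mvf); m1 <- max(mvf)
        if (sim_cl %in% c("AsLB", "VsLB")) {
          a <- sample(-16:4, 1, prob = stats::dnorm(-16:4, 0, 6))
          onset <- max(1L, m0 + a)
        } else {
          lo <- max(1L, m0 - 16L)
          hi <- max(lo, min(Tclip - W + 1L, m1 - 20L))
          onset <- sample(lo:hi, 1)
        }
      }
      onset <- min(onset, Tclip - W + 1L)
      coords[i, , , ] <- sim$track$coords[onset:(onset + W - 1L), , ]
      labels[i] <- cl
    }
  }
  structure(list(coords = coords, labels = factor(labels, levels = cs),
                 plate_format = config$plate_format, fps = config$fps,
                 pixel_pitch_um = config$pixel_pitch_um, W = W),
            class = "clip_set")
}

#' @export
print.clip_set <- function(x, ...) {
  cat(sprintf("<clip_set> %d clips of %d frames (%s):\n",
              dim(x$coords)[1], x$W, x$plate_format))
  print(table(x$labels))
  invisible(x)
}

#' Simulate a full stimulus-response assay
#'
#' Scripts a plate of `n_fish` larvae, each recorded for `n_trials`
#' replicate stimulus acquisitions. A `responder_fraction` share of fish
#' are responders; a responder responds in each trial with probability
#' `trial_response_prob` (with at least one responding trial forced, so
#' the scripted fish-level responder fraction is exact), a non-responder
#' never does.
#'
#' @param kind `"tap"` or `"dark_flash"`.
#' @param n_fish,n_trials plate size (defaults 24 fish x 6 replicates).
#' @param responder_fraction share of responder fish (default 0.75).
#' @param trial_response_prob per-trial response probability of a
#'   responder (default 0.6).
#' @param config a [sim_config()]; `config$seed` makes the assay
#'   deterministic.
#' @return list with `trials` (each: `track`, `labels`, `stimulus`,
#'   `fish`, `trial`, `respond`) and `responder` (logical per fish).
#' @export
simulate_response_assay <- function(kind = c("tap", "dark_flash"),
                                    n_fish = 24, n_trials = 6,
                                    responder_fraction = 0.75,
                                    trial_response_prob = 0.6,
                                    config = sim_config()) {
  kind <- match.arg(kind)
  if (!is.null(config$seed)) set.seed(config$seed)
  trial_cfg <- config
  trial_cfg$seed <- NULL
  n_resp <- round(responder_fraction * n_fish)
  responder <- sample(rep(c(TRUE, FALSE), c(n_resp, n_fish - n_resp)))
  trials <- list()
  for (f in seq_len(n_fish)) {
    resp <- if (responder[f]) {
      v <- stats::runif(n_trials) < trial_response_prob
      if (!any(v)) v[sample(n_trials, 1)] <- TRUE
      v
    } else rep(FALSE, n_trials)
    for (t in seq_len(n_trials)) {
      sim <- make_stimulus_trial(kind, resp[t], trial_cfg,
                                 well_id = sprintf("F%02d", f),
                                 acquisition_id = sprintf("T%d", t))
      sim$fish <- f; sim$trial <- t; sim$respond <- resp[t]
      trials[[length(trials) + 1L]] <- sim
    }
  }
  list(trials = trials, responder = responder, kind = kind)
}

#' Random spontaneous-behavior script
#'
#' Draws a bout sequence for a spontaneous recording: roughly one movement
#' bout per second, with class odds matching the relative spontaneous
#' bout mix (scoots most common, then turns, with occasional
#' startle-like bouts).
#'
#' @param config a [sim_config()] (uses `acquisition_s`; does not seed).
#' @param bout_rate_hz mean bout initiation rate.
#' @return a [behavior_script()].
#' @export
make_spontaneous_script <- function(config = sim_config(acquisition_s = 60),
                                    bout_rate_hz = 0.9) {
  probs <- c(scoot = 0.616, turn = 0.282, AsLB = 0.055, VsLB = 0.047)
  segs <- list()
  t <- 0.4
  while (TRUE) {
    t <- t + stats::rexp(1, bout_rate_hz) + 0.15
    cl <- sample(names(probs), 1, prob = probs)
    dur <- .class_defaults[[cl]]$duration_s
    lat_max <- if (cl == "VsLB") 0.5 else 0.015
    if (t + dur + lat_max > config$acquisition_s - 0.1) break
    segs[[length(segs) + 1L]] <- list(class = cl, onset_s = t)
    t <- t + dur + lat_max
  }
  behavior_script(segs, acquisition_s = config$acquisition_s)
}
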