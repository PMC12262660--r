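# From per-window calls to ethograms, bouts and response rates.
#
# Majority voting aligns window calls to real time: frame t receives the
# most frequent call among all stride-1 windows overlapping t, which
# removes single-window flicker and centers calls on the frames where the
# behavior actually happens. Ties break by a fixed class priority that
# favors the rarer stimulus classes (VsLB > AsLB > turn > scoot >
# movement > stationary) so startles are not voted away.

.vote_priority <- c("VsLB", "AsLB", "turn", "scoot", "movement", "stationary")

#' Majority-vote window calls into a per-frame call series
#'
#' With the N - W stride-1 window convention, windows cover frames 1
#' through N - 1; the final frame has no covering window and is absent
#' from the output.
#'
#' @param window_calls factor/character of per-window calls, window i
#'   (start frame i) covering frames `[i, i + W - 1]`.
#' @param W window length in frames.
#' @return data.frame with `frame`, `call` (factor) and `n_votes` (votes
#'   for the winning call).
#' @export
majority_vote <- function(window_calls, W) {
  calls <- as.factor(window_calls)
  m <- length(calls)
  if (m == 0) stop("no window calls", call. = FALSE)
  n_cov <- m + W - 1L                  # covered frames
  levs <- levels(calls)
  ord <- c(intersect(.vote_priority, levs), setdiff(levs, .vote_priority))
  t <- seq_len(n_cov)
  lo <- pmax(1L, t - W + 1L)           # first window covering frame t
  hi <- pmin(m, t)                     # last window covering frame t
  counts <- matrix(0L, n_cov, length(ord), dimnames = list(NULL, ord))
  for (cl in ord) {
    cu <- c(0L, cumsum(calls == cl))
    counts[, cl] <- cu[hi + 1L] - cu[lo]
  }
  win <- max.col(counts, ties.method = "first")   # columns pre-ordered by priority
  data.frame(frame = t,
             call = factor(ord[win], levels = levs),
             n_votes = counts[cbind(t, win)])
}

#' Segment a call series into bouts
#'
#' A call bout is a maximal run of identical calls strictly longer than
#' `min_run` frames (runs of exactly `min_run` are dropped; the
#' complementary speed-bout rule in [detect_speed_bouts()] is inclusive,
#' mirroring the distinct wording of the two definitions). When a
#' kinematic series is supplied each bout is annotated with its duration
#' and per-bout maxima.
#'
#' @param series data.frame from [majority_vote()] (columns `frame`,
#'   `call`), or a factor of per-frame calls.
#' @param fps frames per second.
#' @param min_run minimum run length that a bout must exceed (default 5).
#' @param exclude classes to drop from the output (e.g. `"stationary"`),
#'   or NULL to keep all.
#' @param kin optional data.frame from [compute_kinematics()].
#' @return data.frame of bouts: `call`, `start_frame`, `end_frame`
#'   (half-open), `n_frames`, `duration_s`, and, with `kin`,
#'   `max_speed_mm_s` and `max_dheading_deg`.
#' @export
calls_to_bouts <- function(series, fps, min_run = 5, exclude = NULL,
                           kin = NULL) {
  if (is.data.frame(series)) {
    frames <- series$frame
    calls <- as.character(series$call)
  } else {
    calls <- as.character(series)
    frames <- seq_along(calls)
  }
  r <- rle(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths > min_run
  if (!is.null(exclude)) keep <- keep & !(r$values %in% exclude)
  out <- data.frame(call = r$values[keep],
                    start_frame = frames[starts[keep]],
                    end_frame = frames[ends[keep]] + 1L,
                    n_frames = r$lengths[keep])
  out$duration_s <- out$n_frames / fps
  if (!is.null(kin) && nrow(out)) {
    out$max_speed_mm_s <- mapply(function(s, e) {
      v <- kin$speed_mm_s[kin$frame >= s & kin$frame < e]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, out$start_frame, out$end_frame)
    out$max_dheading_deg <- mapply(function(s, e) {
      v <- kin$dheading_deg[kin$frame >= s & kin$frame < e]
      if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE)
    }, out$start_frame, out$end_frame)
  }
  out
}

#' Bouts intersecting a stimulus window
#'
#' Keeps bouts whose frame interval overlaps `[onset, onset + window_s)`
#' by any amount. The default windows are the response windows used for
#' responder calling: 0.25 s after a tap, 1.0 s after a dark flash.
#'
#' @param bouts data.frame from [calls_to_bouts()].
#' @param stimulus a [stimulus_event()].
#' @param fps frames per second.
#' @param window_s response window length in seconds; defaults by
#'   stimulus kind.
#' @return the intersecting subset of `bouts`.
#' @export
stimulus_bouts <- function(bouts, stimulus, fps, window_s = NULL) {
  window_s <- window_s %||%
    switch(stimulus$kind, tap = 0.25, dark_flash = 1.0,
           stop("no response window for stimulus kind ", stimulus$kind,
                call. = FALSE))
  s0 <- stimulus$onset_s
  start_s <- (bouts$start_frame - 1) / fps
  end_s <- (bouts$end_frame - 1) / fps
  bouts[end_s > s0 & start_s < s0 + window_s, , drop = FALSE]
}

#' Stimulus-response rates across fish and trials
#'
#' A trial is responsive when at least one frame inside the response
#' window carries the elicited call (AsLB within 250 ms of a tap, VsLB
#' within 1.0 s of a dark flash); a fish is responsive when any of its
#' replicate trials is. Reported percentages are % responsive trials and
#' % responsive fish.
#'
#' @param calls long data.frame with columns `fish`, `trial`, `frame`,
#'   `call` (per-frame ethograms, e.g. stacked [majority_vote()] output).
#' @param stimulus_kind `"tap"` or `"dark_flash"`.
#' @param fps frames per second.
#' @param onset_s stimulus onset (default 5 s).
#' @param window_s response window; defaults by stimulus kind.
#' @return object of class `response_table`: `trials` (fish, trial,
#'   responsive), `fish` (fish, responsive), `pct_trials`, `pct_fish`.
#' @export
response_rates <- function(calls, stimulus_kind = c("tap", "dark_flash"),
                           fps, onset_s = 5, window_s = NULL) {
  stimulus_kind <- match.arg(stimulus_kind)
  window_s <- window_s %||% switch(stimulus_kind, tap = 0.25, dark_flash = 1.0)
  target <- switch(stimulus_kind, tap = "AsLB", dark_flash = "VsLB")
  tm <- (calls$frame - 1) / fps
  hit <- tm > onset_s & tm <= onset_s + window_s & calls$call == target
  key <- paste(calls$fish, calls$trial, sep = "\x1f")
  resp <- tapply(hit, key, any)
  ids <- do.call(rbind, strsplit(names(resp), "\x1f", fixed = TRUE))
  trials <- data.frame(fish = ids[, 1], trial = ids[, 2],
                       responsive = as.vector(resp))
  fish_resp <- tapply(trials$responsive, trials$fish, any)
  fish <- data.frame(fish = names(fish_resp),
                     responsive = as.vector(fish_resp))
  structure(list(trials = trials, fish = fish,
                 pct_trials = 100 * mean(trials$responsive),
                 pct_fish = 100 * mean(fish$responsive)),
            class = "response_table")
}

#' Classify an assay and compute its response rates
#'
#' Runs the inference pipeline (windowing, alignment, normalization, PCA,
#' forest, majority vote) over every trial of a
#' [simulate_response_assay()] -- or any list of trials with `track`,
#' `fish` and `trial` fields -- and tabulates responder rates.
#'
#' @param bundle a `model_bundle`.
#' @param assay list as returned by [simulate_response_assay()].
#' @param ... passed to [response_rates()] (e.g. `window_s`).
#' @return a `response_table` (see [response_rates()]); the per-frame
#'   ethograms are attached as attribute `"calls"`.
#' @export
assay_response_rates <- function(bundle, assay, ...) {
  rows <- lapply(assay$trials, function(tr) {
    calls <- classify_track(bundle, tr$track)
    mv <- majority_vote(calls$call, W = bundle$W)
    data.frame(fish = tr$fish, trial = tr$trial, frame = mv$frame,
               call = as.character(mv$call))
  })
  calls <- do.call(rbind, rows)
  rt <- response_rates(calls, stimulus_kind = assay$kind,
                       fps = bundle$fps, ...)
  attr(rt, "calls") <- calls
  rt
}

#' @export
print.response_table <- function(x, ...) {
  cat(sprintf("<response_table> %d fish x %d trials: %.1f%% responsive trials, %.1f%% responsive fish\n",
              nrow(x$fish), nrow(x$trials), x$pct_trials, x$pct_fish))
  invisible(x)
}

#' Summary table of an ethogram's bouts
#'
#' Per motor-call class: bout count, the class's proportion of
#' non-stationary bouts, mean +/- SEM bout duration and per-bout maxima.
#' When the total recording length is given, the percentage of recording
#' time spent in active (non-stationary) calls is included.
#'
#' @param bouts data.frame from [calls_to_bouts()] (pooled over fish as
#'   desired).
#' @param total_frames total recorded frames behind `bouts`, or NULL.
#' @return list with `by_class` (data.frame) and `pct_time_active`.
#' @export
ethogram_report <- function(bouts, total_frames = NULL) {
  act <- bouts[bouts$call != "stationary", , drop = FALSE]
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  cls <- sort(unique(act$call))
  rows <- lapply(cls, function(cl) {
    b <- act[act$call == cl, , drop = FALSE]
    data.frame(call = cl, n_bouts = nrow(b),
               proportion = nrow(b) / nrow(act),
               mean_duration_s = mean(b$duration_s),
               sem_duration_s = sem(b$duration_s),
               mean_max_speed_mm_s = if ("max_speed_mm_s" %in% names(b))
                 mean(b$max_speed_mm_s, na.rm = TRUE) else NA_real_,
               mean_max_dheading_deg = if ("max_dheading_deg" %in% names(b))
                 mean(b$max_dheading_deg, na.rm = TRUE) else NA_real_)
  })
  list(by_class = do.call(rbind, rows),
       pct_time_active = if (!is.null(total_frames))
         100 * sum(act$n_frames) / total_frames else NA_real_)
}
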