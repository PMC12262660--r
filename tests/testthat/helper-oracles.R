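# Independent brute-force oracles used to check the vectorized
# implementations. Deliberately naive: plain loops and tallies.

wrap180 <- function(a) {
  w <- ((a + 180) %% 360) - 180
  w[!is.na(w) & w == -180] <- 180
  w
}

# per-frame majority vote by explicit tally over covering windows
brute_vote <- function(calls, W) {
  calls <- as.character(calls)
  m <- length(calls)
  priority <- c("VsLB", "AsLB", "turn", "scoot", "movement", "stationary")
  out <- character(m + W - 1)
  for (t in seq_len(m + W - 1)) {
    cover <- calls[seq_len(m)[pmax(1, t - W + 1):pmin(m, t)]]
    tab <- table(cover)
    winners <- names(tab)[tab == max(tab)]
    ord <- c(intersect(priority, winners), setdiff(sort(winners), priority))
    out[t] <- ord[1]
  }
  out
}

# maximal same-label runs strictly longer than min_run
brute_call_runs <- function(labels, min_run) {
  labels <- as.character(labels)
  out <- list()
  i <- 1
  while (i <= length(labels)) {
    j <- i
    while (j < length(labels) && labels[j + 1] == labels[i]) j <- j + 1
    if (j - i + 1 > min_run)
      out[[length(out) + 1]] <- data.frame(call = labels[i], start_frame = i,
                                           end_frame = j + 1,
                                           n_frames = j - i + 1)
    i <- j + 1
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(call = character(), start_frame = integer(),
               end_frame = integer(), n_frames = integer())
}

# maximal supra-threshold speed runs of at least min_frames
brute_speed_runs <- function(speed, threshold, min_frames) {
  above <- !is.na(speed) & speed > threshold
  out <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      if (j - i + 1 >= min_frames)
        out[[length(out) + 1]] <- data.frame(start_frame = i, end_frame = j + 1,
                                             n_frames = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start_frame = integer(), end_frame = integer(),
               n_frames = integer())
}

# random rigid motion applied to every frame of a coords array (y, x)
apply_rigid <- function(coords, angle_deg, shift_y, shift_x) {
  th <- angle_deg * pi / 180
  y <- coords[, , 1]; x <- coords[, , 2]
  out <- coords
  out[, , 2] <- cos(th) * x - sin(th) * y + shift_x
  out[, , 1] <- sin(th) * x + cos(th) * y + shift_y
  out
}

# all pairwise within-frame keypoint distances of a window/track array
pairwise_dists <- function(coords) {
  apply(coords, 1, function(fr) as.vector(dist(fr)))
}
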