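# Shared fixtures. Heavyweight objects (trained bundles, default corpora)
# are built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# default training corpus for a plate format, fixed seed
default_corpus <- function(fmt) {
  cached(paste0("corpus_", fmt),
         make_training_corpus(config = sim_config(fmt, seed = 2023)))
}

# model trained on the default 90% split, plus its held-out 10%
trained_split <- function(fmt) {
  cached(paste0("split_", fmt), {
    sp <- split_train_test(default_corpus(fmt), 0.9, seed = 2023)
    sp$bundle <- train_behavior_model(sp$train, seed = 2023)
    sp
  })
}

# a small deterministic straight-swimming track: fish heading up (-y),
# moving 1 px/frame, all 8 points collinear
straight_track <- function(n = 60, fps = 160, pitch = 37.8) {
  arc <- c(0, .12, .30, .45, .60, .75, .88, 1) * 90   # px along body
  co <- array(0, c(n, 8, 2))
  for (t in seq_len(n)) {
    co[t, , 1] <- 500 - t + arc          # snout highest (smallest y)
    co[t, , 2] <- 300
  }
  pose_track(co, fps = fps, pixel_pitch_um = pitch)
}

# track built from explicit per-frame center/snout/tip geometry
track_from_headings <- function(headings_deg, center = c(100, 100), d = 30) {
  n <- length(headings_deg)
  co <- array(0, c(n, 8, 2))
  for (t in seq_len(n)) {
    th <- headings_deg[t] * pi / 180
    u <- c(-cos(th), sin(th))            # (y, x) unit bearing
    for (k in 1:8)                       # key point 3 (center) sits at `center`
      co[t, k, ] <- center + (3 - k) / 2.5 * d * u
  }
  pose_track(co)
}
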