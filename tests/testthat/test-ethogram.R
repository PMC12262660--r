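test_that("majority voting matches a hand tally and unanimity", {
  mv <- majority_vote(factor(rep("scoot", 20)), W = 40)
  expect_equal(nrow(mv), 59)              # 20 windows cover 59 frames
  expect_true(all(mv$call == "scoot"))

  # W = 3, calls A A B B B over a 7-frame track: hand-tallied modes
  mv2 <- majority_vote(factor(c("A", "A", "B", "B", "B")), W = 3)
  expect_equal(as.character(mv2$call), c("A", "A", "A", "B", "B", "B", "B"))
  expect_equal(mv2$n_votes, c(1, 2, 2, 2, 3, 2, 1))
})

test_that("exact vote ties break by the fixed class priority", {
  # frame 2 is covered by both windows: one stationary, one VsLB vote
  mv <- majority_vote(factor(c("stationary", "VsLB"),
                             levels = c("stationary", "VsLB")), W = 2)
  expect_equal(as.character(mv$call[2]), "VsLB")
  mv2 <- majority_vote(factor(c("scoot", "turn"),
                              levels = c("scoot", "turn")), W = 2)
  expect_equal(as.character(mv2$call[2]), "turn")
})

test_that("majority voting equals the brute-force tally on random inputs", {
  set.seed(50)
  classes <- c("stationary", "scoot", "turn", "AsLB", "VsLB")
  for (i in 1:200) {
    m <- sample(5:60, 1)
    W <- sample(2:12, 1)
    calls <- factor(sample(classes, m, replace = TRUE), levels = classes)
    got <- majority_vote(calls, W)
    expect_identical(as.character(got$call), brute_vote(calls, W))
  }
})

test_that("voting never increases label transitions (smoothing)", {
  set.seed(51)
  classes <- c("stationary", "scoot", "AsLB")
  transitions <- function(x) sum(head(x, -1) != tail(x, -1))
  for (i in 1:100) {
    calls <- sample(classes, 80, replace = TRUE)
    sm <- as.character(majority_vote(factor(calls, levels = classes), W = 40)$call)
    expect_lte(transitions(sm), transitions(calls))
  }
})

test_that("call bouts require runs strictly longer than min_run", {
  f <- function(x) calls_to_bouts(factor(x), fps = 160, min_run = 5)
  run5 <- f(c(rep("stationary", 10), rep("turn", 5), rep("stationary", 10)))
  expect_false("turn" %in% run5$call)
  run6 <- f(c(rep("stationary", 10), rep("turn", 6), rep("stationary", 10)))
  expect_equal(run6$call, c("stationary", "turn", "stationary"))
  expect_equal(run6$n_frames[2], 6)
  expect_equal(run6$start_frame[2], 11)
  expect_equal(run6$end_frame[2], 17)     # half-open
  expect_equal(run6$duration_s[2], 6 / 160)
  # exclusion drops stationary bouts
  ex <- calls_to_bouts(factor(c(rep("stationary", 10), rep("scoot", 8))),
                       fps = 160, min_run = 5, exclude = "stationary")
  expect_equal(ex$call, "scoot")
})

test_that("call-bout segmentation equals the brute-force run scan", {
  set.seed(52)
  classes <- c("stationary", "scoot", "turn")
  for (i in 1:200) {
    x <- sample(classes, sample(10:100, 1), replace = TRUE,
                prob = c(.7, .2, .1))
    got <- calls_to_bouts(factor(x), fps = 160, min_run = 5)
    want <- brute_call_runs(x, 5)
    expect_equal(got[c("call", "start_frame", "end_frame", "n_frames")],
                 want, ignore_attr = TRUE)
  }
})

test_that("stimulus-window bout selection uses any-overlap semantics", {
  fps <- 160
  fr <- function(s) round(s * fps) + 1     # seconds -> 1-based frame
  bouts <- data.frame(call = c("AsLB", "scoot", "VsLB"),
                      start_frame = fr(c(4.9, 5.3, 5.9)),
                      end_frame = fr(c(5.1, 5.5, 6.2)),
                      n_frames = 1)
  tap <- stimulus_event("tap", 5)
  sel <- stimulus_bouts(bouts, tap, fps)           # window 5.0-5.25
  expect_equal(sel$call, "AsLB")
  flash <- stimulus_event("dark_flash", 5)
  sel2 <- stimulus_bouts(bouts, flash, fps)        # window 5.0-6.0
  expect_setequal(sel2$call, c("AsLB", "scoot", "VsLB"))
})

test_that("responder definitions: trial window hit, fish = OR over trials", {
  fps <- 160
  mk <- function(fish, trial, aslb_at_s = NULL) {
    frames <- 1:1599
    call <- rep("stationary", length(frames))
    if (!is.null(aslb_at_s)) call[round(aslb_at_s * fps) + 1] <- "AsLB"
    data.frame(fish = fish, trial = trial, frame = frames, call = call)
  }
  # fish 1: responds in trial 2 only (inside window); fish 2: never;
  # fish 3: AsLB outside the 250 ms window does not count
  calls <- rbind(mk(1, 1), mk(1, 2, 5.1), mk(1, 3), mk(1, 4), mk(1, 5), mk(1, 6),
                 mk(2, 1), mk(2, 2),
                 mk(3, 1, 5.4))
  rt <- response_rates(calls, "tap", fps = fps)
  expect_equal(rt$trials$responsive[rt$trials$fish == 1 & rt$trials$trial == 2],
               TRUE)
  expect_equal(sum(rt$trials$responsive), 1)
  expect_equal(rt$fish$responsive, c(TRUE, FALSE, FALSE))
  # fish-level = OR of its trials
  for (f in rt$fish$fish)
    expect_equal(rt$fish$responsive[rt$fish$fish == f],
                 any(rt$trials$responsive[rt$trials$fish == f]))
  expect_equal(rt$pct_fish, 100 / 3)
  # no elicited calls anywhere -> zero on both metrics
  rt0 <- response_rates(mk(1, 1), "tap", fps = fps)
  expect_equal(rt0$pct_trials, 0)
  expect_equal(rt0$pct_fish, 0)
})

test_that("ethogram report computes proportions, durations and active time", {
  bouts <- data.frame(call = c("scoot", "scoot", "scoot", "turn", "stationary"),
                      start_frame = c(1, 100, 200, 300, 400),
                      end_frame = c(41, 140, 240, 340, 800),
                      n_frames = c(40, 40, 40, 40, 400),
                      duration_s = c(40, 40, 40, 40, 400) / 160)
  rep <- ethogram_report(bouts, total_frames = 1600)
  by_cl <- rep$by_class
  expect_equal(by_cl$proportion[by_cl$call == "scoot"], 0.75)
  expect_equal(by_cl$proportion[by_cl$call == "turn"], 0.25)
  expect_equal(by_cl$mean_duration_s[by_cl$call == "scoot"], 0.25)
  expect_false("stationary" %in% by_cl$call)
  expect_equal(rep$pct_time_active, 100 * 160 / 1600)
})

test_that("ethogram bouts recover scripted segments on a spontaneous track", {
  sp <- trained_split("P24")
  cfg <- sim_config("P24", acquisition_s = 20, seed = 60)
  sim <- simulate_track(make_spontaneous_script(cfg), cfg)
  calls <- classify_track(sp$bundle, sim$track)
  mv <- majority_vote(calls$call, W = 40)
  bouts <- calls_to_bouts(mv, fps = 160, min_run = 5, exclude = "stationary")
  # every scripted movement segment of >= 10 frames overlaps a detected
  # bout of the same class for most of its frames
  truth <- brute_call_runs(sim$labels[seq_len(nrow(mv))], 9)
  truth <- truth[truth$call != "stationary", ]
  overlap <- vapply(seq_len(nrow(truth)), function(i) {
    b <- bouts[bouts$call == truth$call[i], , drop = FALSE]
    if (!nrow(b)) return(0)
    max(pmin(b$end_frame, truth$end_frame[i]) -
        pmax(b$start_frame, truth$start_frame[i])) / truth$n_frames[i]
  }, numeric(1))
  expect_gte(mean(overlap >= 0.9), 0.9)
})
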