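test_that("midline_pose places a straight fish along its heading", {
  body <- body_model(3.7)
  for (hd in c(0, 90, -135)) {
    co <- midline_pose(c(1, 2), hd, rep(0, 7), body)
    # collinear: all cross products of consecutive segments vanish
    seg <- diff(co)
    cross <- seg[-1, 1] * seg[-7, 2] - seg[-1, 2] * seg[-7, 1]
    expect_lt(max(abs(cross)), 1e-12)
    # pairwise consecutive distances = body_length * delta arc
    expect_equal(sqrt(rowSums(seg^2)), 3.7 * diff(body$arc_fractions),
                 tolerance = 1e-12)
    # center key point anchored at the requested position
    expect_equal(co[3, ], c(1, 2), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("midline_pose chain geometry: 180-degree total bend reverses the tail", {
  body <- body_model()
  hd <- 30
  co <- midline_pose(c(0, 0), hd, rep(180 / 7, 7), body)
  # final tail segment now points along +heading (straight fish: -heading)
  seg <- co[8, ] - co[7, ]
  dir <- atan2(seg[2], -seg[1]) * 180 / pi
  expect_equal(dir, hd, tolerance = 1e-9)
})

test_that("mirrored bend profiles mirror coordinates about the heading axis", {
  body <- body_model()
  bend <- c(10, -5, 20, 15, -10, 25, 5)
  a <- midline_pose(c(0, 0), 0, bend, body)    # heading up: axis is x = 0
  b <- midline_pose(c(0, 0), 0, -bend, body)
  expect_equal(a[, 1], b[, 1], tolerance = 1e-12)
  expect_equal(a[, 2], -b[, 2], tolerance = 1e-12)
})

test_that("class templates satisfy their defining kinematics (noiseless)", {
  cfg <- sim_config("P24", noise_sigma_um = 0, seed = 99)

  # all-stationary: center speed < 0.5 mm/s
  s <- simulate_track(behavior_script(list(), 10), cfg)
  kin <- compute_kinematics(s$track)
  expect_lt(max(kin$speed_mm_s, na.rm = TRUE), 0.5)

  # scoot at scripted peak 10 mm/s measured within 1 mm/s, small net heading
  sc <- behavior_script(list(list(class = "scoot", onset_s = 1,
                                  params = list(peak_speed = 10))), 10)
  s2 <- simulate_track(sc, cfg)
  kin2 <- compute_kinematics(s2$track)
  expect_equal(max(kin2$speed_mm_s, na.rm = TRUE), 10, tolerance = 0.1)
  idx <- which(s2$labels == "scoot")
  net <- abs(wrap180(kin2$heading_deg[max(idx)] - kin2$heading_deg[min(idx)]))
  expect_lt(net, 20)

  # turn: 30-90 deg reorientation, low displacement
  tn <- behavior_script(list(list(class = "turn", onset_s = 1)), 10)
  s3 <- simulate_track(tn, cfg)
  kin3 <- compute_kinematics(s3$track)
  idx <- which(s3$labels == "turn")
  net <- abs(wrap180(kin3$heading_deg[max(idx)] - kin3$heading_deg[min(idx) - 1]))
  expect_gt(net, 30); expect_lt(net, 90)

  # AsLB: latency < 15 ms; peak speed and per-frame heading change exceed
  # a default scoot's by >= 5x
  ref <- behavior_script(list(list(class = "scoot", onset_s = 1,
                                   params = list(peak_speed = 8))), 10)
  sref <- simulate_track(ref, cfg)
  kref <- compute_kinematics(sref$track)
  as <- behavior_script(list(list(class = "AsLB", onset_s = 5)), 10)
  s4 <- simulate_track(as, cfg)
  lat <- (which(s4$labels == "AsLB")[1] - 1) / 160 - 5
  expect_lt(lat, 0.015)
  kin4 <- compute_kinematics(s4$track)
  expect_gte(max(kin4$speed_mm_s, na.rm = TRUE),
             5 * max(kref$speed_mm_s[sref$labels == "scoot"]))
  expect_gte(max(kin4$dheading_deg[s4$labels == "AsLB"], na.rm = TRUE),
             5 * max(kref$dheading_deg[sref$labels == "scoot"], na.rm = TRUE))

  # VsLB: onset latency within 150-500 ms, large heading change
  vs <- behavior_script(list(list(class = "VsLB", onset_s = 5)), 10)
  s5 <- simulate_track(vs, cfg)
  lat5 <- (which(s5$labels == "VsLB")[1] - 1) / 160 - 5
  expect_gte(lat5, 0.15); expect_lte(lat5, 0.5)
  kin5 <- compute_kinematics(s5$track)
  idx <- which(s5$labels == "VsLB")
  net5 <- abs(wrap180(kin5$heading_deg[max(idx)] - kin5$heading_deg[min(idx) - 1]))
  expect_gt(net5, 90)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config("P96", seed = 123)
  sc <- behavior_script(list(list(class = "scoot", onset_s = 2)), 10)
  a <- simulate_track(sc, cfg)
  b <- simulate_track(sc, cfg)
  expect_identical(a$track$coords, b$track$coords)
  expect_identical(a$labels, b$labels)
})

test_that("keypoint noise is calibrated: RMS radial deviation ~ noise_sigma_um", {
  # noise is temporally autocorrelated, so pool independent simulations
  # to get enough effective samples for a tight RMS estimate
  sq <- unlist(lapply(1:20, function(s) {
    sim <- simulate_track(behavior_script(list(), 10),
                          sim_config("P24", seed = 1000 + s))   # sigma 70 um
    (sim$track$coords - sim$noiseless)^2
  }))
  n_radial <- length(sq) / 2
  expect_gte(n_radial, 1e4)
  rms <- sqrt(2 * mean(sq)) * 37.8       # radial = sqrt(y^2 + x^2) deviation
  expect_gt(rms, 65); expect_lt(rms, 75)
})

test_that("ground-truth labels and emitted kinematics agree per segment", {
  set.seed(7)
  script <- make_spontaneous_script(sim_config("P24", acquisition_s = 30))
  s <- simulate_track(script, sim_config("P24", acquisition_s = 30,
                                         noise_sigma_um = 0, seed = 77))
  kin <- compute_kinematics(s$track)
  # every labeled movement frame coincides with elevated speed somewhere
  # in its segment, and stationary stretches stay slow
  expect_lt(max(kin$speed_mm_s[s$labels == "stationary"], na.rm = TRUE), 2.5)
  for (cl in c("scoot", "AsLB", "VsLB"))
    if (any(s$labels == cl))
      expect_gt(max(kin$speed_mm_s[s$labels == cl], na.rm = TRUE), 2)
})

test_that("stimulus trials carry the elicited class in the response window", {
  cfg <- sim_config("P24", seed = 5)
  tm <- function(lab, labels) (which(labels == lab) - 1) / 160
  tap <- make_stimulus_trial("tap", TRUE, cfg)
  expect_true(any(tm("AsLB", tap$labels) > 5 & tm("AsLB", tap$labels) <= 5.25))
  df <- make_stimulus_trial("dark_flash", TRUE, cfg)
  expect_true(any(tm("VsLB", df$labels) > 5 & tm("VsLB", df$labels) <= 6))
  non <- make_stimulus_trial("tap", FALSE, cfg)
  expect_false(any(non$labels %in% c("AsLB", "VsLB")))
  expect_equal(tap$stimulus$kind, "tap")
  expect_equal(tap$stimulus$onset_s, 5)
})

test_that("training corpora have the documented default sizes", {
  p24 <- default_corpus("P24")
  expect_equal(dim(p24$coords)[1], 440)         # 66+102+75+60+137
  expect_equal(as.vector(table(p24$labels)), c(66, 102, 75, 60, 137))
  p96 <- default_corpus("P96")
  expect_equal(dim(p96$coords)[1], 1397)        # 432+486+170+309
  expect_equal(levels(p96$labels),
               c("stationary", "movement", "AsLB", "VsLB"))

  small <- make_training_corpus(c(scoot = 3), sim_config("P24", seed = 1))
  expect_equal(as.character(small$labels), rep("scoot", 3))
  expect_error(make_training_corpus(c(movement = 5), sim_config("P24", seed = 1)),
               "unknown class")
})

test_that("scripts reject overlaps and out-of-bounds segments", {
  expect_error(behavior_script(list(list(class = "scoot", onset_s = 9.9)), 10),
               "exceeds acquisition")
  expect_error(behavior_script(list(list(class = "scoot", onset_s = 1),
                                    list(class = "turn", onset_s = 1.1)), 10),
               "overlap")
  expect_error(behavior_script(list(list(class = "sprint", onset_s = 1)), 10),
               "unknown behavior class")
})
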