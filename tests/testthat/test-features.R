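make_ds <- function(df, arena = c(370, 200)) tracking_dataset(df, arena = arena)

test_that("ideal head-to-head geometry produces the textbook feature values", {
  rec <- data.frame(bee_id = c(1L, 2L), frame = 0L, time = 0,
                    x = c(100, 110), y = 50, orientation = c(0, 180))
  pf <- compute_per_frame(make_ds(rec), body_length = 13)
  a <- pf[pf$bee_id == 1, ]
  expect_equal(a$dist_center, 10)
  expect_equal(a$facing_angle, 0)
  expect_equal(a$partner_facing_angle, 0)
  expect_equal(a$orientation_diff, 180)
  expect_equal(a$dist_head, 3)  # heads 6.5 mm inward: |10 - 13| = 3 mm apart
  expect_true(head_to_head(pf)[1])

  # side-by-side parallel bees: facing angles 90 degrees, not head-to-head
  rec2 <- data.frame(bee_id = c(1L, 2L), frame = 0L, time = 0,
                     x = 100, y = c(50, 60), orientation = 0)
  pf2 <- compute_per_frame(make_ds(rec2))
  expect_equal(pf2$facing_angle[1], 90)
  expect_equal(pf2$orientation_diff[1], 0)
  expect_false(any(head_to_head(pf2)))
})

test_that("kinematics use consecutive frames and the social channels go missing when alone", {
  rec <- data.frame(bee_id = 1L, frame = 0:2, time = (0:2) / 4,
                    x = c(100, 100.9, 101.8), y = 50, orientation = 45)
  pf <- compute_per_frame(make_ds(rec))
  expect_true(is.na(pf$speed[1]))
  expect_equal(pf$speed[2], 0.9 * 4)   # the printed mean step at 4 fps
  expect_equal(pf$angular_speed[2], 0)
  expect_true(all(is.na(pf$dist_center)))
  expect_true(all(is.na(pf$facing_angle)))
  expect_equal(pf$n_neighbors, c(0, 0, 0))

  still <- data.frame(bee_id = 1L, frame = 0:1, time = c(0, 0.25),
                      x = 5, y = 5, orientation = 300)
  pf2 <- compute_per_frame(make_ds(still))
  expect_equal(pf2$speed[2], 0)
  expect_equal(pf2$angular_speed[2], 0)
})

test_that("features are invariant under rigid motion of the arena frame", {
  set.seed(88)
  n <- 40
  rec <- data.frame(bee_id = rep(1:4, each = n), frame = rep(0:(n - 1), 4),
                    time = rep(0:(n - 1), 4) / 4,
                    x = rep(c(100, 120, 150, 180), each = n) + rnorm(4 * n, 0, 2),
                    y = rep(c(100, 110, 140, 90), each = n) + rnorm(4 * n, 0, 2),
                    orientation = runif(4 * n, 0, 360))
  base <- compute_per_frame(make_ds(rec, arena = c(2000, 2000)))
  th <- 63 * pi / 180
  rot <- rec
  rot$x <- 500 + rec$x * cos(th) - rec$y * sin(th)
  rot$y <- 200 + rec$x * sin(th) + rec$y * cos(th)
  rot$orientation <- (rec$orientation + 63) %% 360
  got <- compute_per_frame(make_ds(rot, arena = c(2000, 2000)))
  for (ch in attr(base, "channels"))
    expect_equal(got[[ch]], base[[ch]], tolerance = 1e-8)
})

test_that("mutual closest pairs see symmetric distances and orientation differences", {
  pf <- compute_per_frame(sim_medium()$tracking)
  one <- pf[pf$frame == 100, ]
  for (i in seq_len(nrow(one))) {
    j <- match(one$closest_id[i], one$bee_id)
    if (is.na(j) || one$closest_id[j] != one$bee_id[i]) next
    expect_equal(one$dist_center[i], one$dist_center[j], tolerance = 1e-9)
    expect_equal(one$orientation_diff[i], one$orientation_diff[j],
                 tolerance = 1e-9)
  }
})

test_that("closing speed is the discrete derivative of centre distance", {
  set.seed(5)
  rec <- data.frame(bee_id = rep(1:2, each = 30), frame = rep(0:29, 2),
                    time = rep(0:29, 2) / 4,
                    x = c(100 + cumsum(rnorm(30)), 120 + cumsum(rnorm(30))),
                    y = c(100 + cumsum(rnorm(30)), 100 + cumsum(rnorm(30))),
                    orientation = runif(60, 0, 360))
  pf <- compute_per_frame(make_ds(rec, arena = c(1000, 1000)))
  d1 <- pf$dist_center[pf$bee_id == 1]
  cs <- pf$closing_speed[pf$bee_id == 1]
  expect_equal(cs[-1], diff(d1) * 4, tolerance = 1e-9)
})

test_that("window statistics satisfy their defining identities", {
  pf <- compute_per_frame(make_ds(data.frame(
    bee_id = 1L, frame = 0:19, time = (0:19) / 4,
    x = 100 + (0:19) * 0.5, y = 50, orientation = 0)))
  # constant channel: mean = value, sd = 0, diff = 0 at every radius
  pf$speed[] <- 3.6  # overwrite to a constant incl. first frame
  wf <- compute_window_features(pf, radii = c(0, 2))
  expect_equal(wf$speed_w2_mean, rep(3.6, 20))
  expect_equal(wf$speed_w2_sd, rep(0, 20), tolerance = 1e-6)
  expect_equal(wf$speed_w2_diff, rep(0, 20), tolerance = 1e-6)
  # radius 0 reproduces the raw channel exactly
  expect_equal(wf$speed_w0_mean, pf$speed)
  expect_equal(wf$speed_w0_min, pf$speed)
  expect_equal(wf$speed_w0_max, pf$speed)
  expect_equal(wf$speed_w0_sd, rep(0, 20))
  # ramp oracle: channel = frame index, windowed max at t is t + r inside
  pf$speed <- as.numeric(pf$frame)
  wf <- compute_window_features(pf, radii = 2)
  interior <- pf$frame >= 2 & pf$frame <= 17
  expect_equal(wf$speed_w2_max[interior], pf$frame[interior] + 2)
  expect_equal(wf$speed_w2_min[interior], pf$frame[interior] - 2)
  # min <= mean <= max everywhere
  expect_true(all(wf$speed_w2_min <= wf$speed_w2_mean + 1e-12))
  expect_true(all(wf$speed_w2_mean <= wf$speed_w2_max + 1e-12))
  # column count: channels x radii x 5
  wf2 <- compute_window_features(pf, radii = c(1, 2, 4))
  expect_equal(length(attr(wf2, "channels")),
               length(attr(pf, "channels")) * 3 * 5)
})

test_that("window statistics skip missing frames instead of fabricating them", {
  rec <- data.frame(bee_id = 1L, frame = c(0L, 1L, 3L, 4L),
                    time = c(0, 0.25, 0.75, 1),
                    x = c(10, 11, 13, 14), y = 10, orientation = 0)
  pf <- compute_per_frame(make_ds(rec))
  pf$speed <- c(1, 2, 8, 9)
  wf <- compute_window_features(pf, radii = 1)
  # at frame 3 the window {2,3,4} has a missing frame 2: mean over {8, 9}
  expect_equal(wf$speed_w1_mean[wf$frame == 3], 8.5)
  # at frame 1 the window {0,1,2} sees only {1, 2}
  expect_equal(wf$speed_w1_mean[wf$frame == 1], 1.5)
})

test_that("head-to-head boundary is strict beyond the thresholds", {
  rec <- data.frame(bee_id = c(1L, 2L), frame = 0L, time = 0,
                    x = c(100, 100 + 13 + 4.6), y = 50,
                    orientation = c(0, 180))
  pf <- compute_per_frame(make_ds(rec), body_length = 13)
  expect_equal(pf$dist_head[1], 4.6)
  expect_false(any(head_to_head(pf, max_head_dist = 4.5)))
  expect_true(all(head_to_head(pf, max_head_dist = 4.6)))
})

test_that("planted encounters are geometrically separable from NEB time", {
  sim <- sim_medium()
  pf <- compute_per_frame(sim$tracking)
  h2h <- head_to_head(pf)
  key <- paste(pf$bee_id, pf$frame)
  lab <- sim$labels
  ebk <- interval_keys(lab, which(lab$group == "EB"))
  nebk <- interval_keys(lab, which(lab$group == "NEB"))
  expect_gte(mean(h2h[key %in% ebk]), 0.99)
  expect_lte(mean(h2h[key %in% nebk]), 0.01)
})
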