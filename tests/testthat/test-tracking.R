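test_that("empty and populated datasets report their shape", {
  ds <- tracking_dataset()
  expect_equal(nrow(ds), 0)
  expect_length(attr(ds, "frame_range"), 0)

  # a 100-bee, 1200-frame (5 min at 4 fps) grid loads with full frame range
  n_bees <- 100; n_frames <- 1200
  big <- data.frame(bee_id = rep(seq_len(n_bees), each = n_frames),
                    frame = rep(0:(n_frames - 1), n_bees),
                    time = rep(0:(n_frames - 1), n_bees) / 4,
                    x = 100, y = 100, orientation = 90)
  ds <- tracking_dataset(big)
  expect_equal(attr(ds, "frame_range"), c(0L, 1199L))
  expect_equal(length(unique(ds$bee_id)), 100)
})

test_that("tracking tables round-trip through write/read exactly", {
  ds <- tracking_dataset(toy_records())
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracking(ds, path)
  back <- read_tracking(path)
  for (col in c("bee_id", "frame", "time", "x", "y", "orientation"))
    expect_identical(back[[col]], ds[[col]])

  # empty dataset writes a header-only file that reads back empty
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_tracking(tracking_dataset(), p2)
  expect_length(readLines(p2), 1)
  expect_equal(nrow(read_tracking(p2)), 0)

  # data rows come out in (bee, frame) order, one per detection
  expect_equal(length(readLines(path)) - 1L, nrow(ds))
})

test_that("invalid records are rejected with informative errors", {
  rec <- toy_records()
  bad <- rec; bad$orientation[2] <- 360
  expect_error(tracking_dataset(bad), "orientation")
  bad <- rec; bad$frame[2] <- 0L
  expect_error(tracking_dataset(bad), "duplicate")
  bad <- rec; bad$x[1] <- 999
  expect_error(tracking_dataset(bad), "arena")
  expect_error(read_tracking(tempfile("nope")), "no such file")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("bee_id,frame,time,x,y,orientation", "1,0,0,10,10,oops"), p)
  expect_error(read_tracking(p), "line")
})

test_that("gap interpolation fills short gaps with circular shortest arcs", {
  rec <- data.frame(bee_id = 1L, frame = c(10L, 12L), time = c(2.5, 3),
                    x = c(0, 2), y = c(0, 0), orientation = c(350, 10))
  ds <- tracking_dataset(rec)
  expect_identical(as.data.frame(interpolate_gaps(ds, 0)), as.data.frame(ds))

  out <- interpolate_gaps(ds, 1)
  mid <- out[out$frame == 11L, ]
  expect_equal(nrow(mid), 1)
  expect_equal(mid$x, 1)
  expect_equal(mid$y, 0)
  expect_equal(mid$orientation, 0)  # shortest arc through 360, not 180
  expect_true(mid$synthetic)
  # existing records are untouched
  orig <- as.data.frame(out[!out$synthetic, names(rec)])
  rownames(orig) <- NULL
  expect_identical(orig, as.data.frame(ds[, names(rec)]))

  # a gap of max_gap + 1 missing frames stays a gap
  rec2 <- data.frame(bee_id = 1L, frame = c(0L, 4L), time = c(0, 1),
                     x = c(0, 1), y = c(0, 1), orientation = c(0, 0))
  expect_equal(nrow(interpolate_gaps(tracking_dataset(rec2), 2)), 2)
  expect_equal(nrow(interpolate_gaps(tracking_dataset(rec2), 3)), 5)
})

test_that("detection rate is the percentage of detected frames in a window", {
  ds <- tracking_dataset(toy_records())
  expect_equal(detection_rate(ds, 1, c(0, 2)), 100)
  expect_equal(detection_rate(ds, 2, c(0, 2)), 100 * 2 / 3)
  expect_equal(detection_rate(ds, 2, c(5, 9)), 0)
  expect_error(detection_rate(ds, 99, c(0, 2)), "unknown bee_id")

  # the printed moving-bee scale: 218 of 240 frames is 90.83 %
  rec <- data.frame(bee_id = 1L, frame = 0:239, time = (0:239) / 4,
                    x = 10, y = 10, orientation = 0)
  rec <- rec[-(1:22), ]
  expect_equal(detection_rate(tracking_dataset(rec), 1, c(0, 239)),
               100 * 218 / 240, tolerance = 1e-12)
})

test_that("frame-step statistics use wrapped orientation differences", {
  rec <- data.frame(bee_id = 1L, frame = 0:1, time = c(0, 0.25),
                    x = c(0, 3), y = c(0, 4), orientation = c(10, 350))
  fs <- frame_step_stats(tracking_dataset(rec))
  expect_equal(fs$mean_step, 5)       # 3-4-5 triangle
  expect_equal(fs$mean_dori, 20)      # shortest arc across 0
  expect_equal(fs$n_steps, 1)

  still <- data.frame(bee_id = 1L, frame = 0:9, time = (0:9) / 4,
                      x = 5, y = 5, orientation = 90)
  fs <- frame_step_stats(tracking_dataset(still))
  expect_equal(fs$mean_step, 0)
  expect_equal(fs$mean_dori, 0)

  gap <- data.frame(bee_id = 1L, frame = c(0L, 5L), time = c(0, 2),
                    x = c(0, 1), y = 0, orientation = 0)
  expect_error(frame_step_stats(tracking_dataset(gap)), "consecutive")
})

test_that("frame-step statistics are invariant under rigid motions", {
  set.seed(77)
  rec <- data.frame(bee_id = rep(1:3, each = 50),
                    frame = rep(0:49, 3),
                    time = rep(0:49, 3) / 4,
                    x = 100 + cumsum(rnorm(150, 0, 0.5)),
                    y = 100 + cumsum(rnorm(150, 0, 0.5)),
                    orientation = (cumsum(rnorm(150, 0, 5))) %% 360)
  ds <- tracking_dataset(rec, arena = c(1000, 1000))
  base <- frame_step_stats(ds)
  for (ang in c(30, 117)) {
    th <- ang * pi / 180
    rot <- rec
    rot$x <- 300 + rec$x * cos(th) - rec$y * sin(th)
    rot$y <- 300 + rec$x * sin(th) + rec$y * cos(th)
    rot$orientation <- (rec$orientation + ang) %% 360
    got <- frame_step_stats(tracking_dataset(rot, arena = c(1000, 1000)))
    expect_equal(got$mean_step, base$mean_step, tolerance = 1e-9)
    expect_equal(got$mean_dori, base$mean_dori, tolerance = 1e-9)
  }
})

test_that("the shipped example fixtures parse as documented", {
  tr <- read_tracking(system.file("extdata", "example_tracks.csv",
                                  package = "beetrax"))
  expect_equal(nrow(tr), 5)
  expect_equal(length(unique(tr$bee_id)), 3)
  la <- read_labels(system.file("extdata", "example_labels.csv",
                                package = "beetrax"))
  expect_equal(la$group, c("EB", "EB", "EB", "NEB", "NEB"))
  expect_true(is.na(la$partner_id[4]))
})

test_that("label intervals validate and round-trip", {
  li <- label_intervals(c(1L, 2L, 3L), c("trophallaxis", "sitting", "begging"),
                        c(0L, 10L, 20L), c(39L, 19L, 25L),
                        partner_id = c(2L, NA, 4L))
  expect_equal(li$group, c("EB", "NEB", "EB"))
  expect_equal(interval_duration(li), c(10, 2.5, 1.5))
  p <- withr::local_tempfile(fileext = ".csv")
  write_labels(li, p)
  back <- read_labels(p)
  expect_equal(as.data.frame(back), as.data.frame(li))
  expect_error(label_intervals(1L, "dancing", 0L, 1L), "unknown behaviour")
  expect_error(label_intervals(1L, "sitting", 5L, 1L), "start_frame")
  expect_error(behavior_group("waggle"), "unknown behaviour")
})
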