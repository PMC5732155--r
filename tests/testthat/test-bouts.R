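frame_labels <- function(bee, frames_eb, range = c(0, 59)) {
  df <- data.frame(bee_id = bee, frame = range[1]:range[2])
  df$label <- ifelse(df$frame %in% frames_eb, "EB", "NEB")
  df
}

test_that("bout extraction merges short gaps and drops short runs", {
  expect_equal(nrow(extract_bouts(frame_labels(1L, integer()))), 0)

  fl <- frame_labels(1L, c(10:15, 17:20))
  b <- extract_bouts(fl, gap_fill = 2, min_len = 1)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$start_frame, b$end_frame), c(10, 20))

  b0 <- extract_bouts(fl, gap_fill = 0, min_len = 1)
  expect_equal(b0$start_frame, c(10, 17))

  # a gap of gap_fill + 1 NEB frames stays a split
  fl2 <- frame_labels(1L, c(10:12, 16:18))
  expect_equal(nrow(extract_bouts(fl2, gap_fill = 2)), 2)
  expect_equal(nrow(extract_bouts(fl2, gap_fill = 3)), 1)

  # min_len drops merged runs that are still too short
  expect_equal(nrow(extract_bouts(frame_labels(1L, 5:6), min_len = 3)), 0)

  # 32 frames at 4 fps is the 8 s trophallaxis-median scale
  b8 <- extract_bouts(frame_labels(1L, 0:31), gap_fill = 0)
  expect_equal(b8$duration_s, 8)
})

test_that("bout extraction inverts frame-label expansion", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(1:5, 1)
    starts <- sort(sample(seq(0, 80, by = 12), n))
    lens <- sample(1:6, n, replace = TRUE)
    bouts <- data.frame(bee_id = sample(1:3, n, replace = TRUE),
                        start_frame = starts,
                        end_frame = pmin(starts + lens - 1L, starts + 10L))
    fl <- bouts_to_frame_labels(bouts, 1:3, c(0, 95))
    back <- extract_bouts(fl, gap_fill = 0, min_len = 1)
    got <- as.data.frame(back)[order(back$bee_id, back$start_frame),
                               c("bee_id", "start_frame", "end_frame")]
    want <- bouts[order(bouts$bee_id, bouts$start_frame),
                  c("bee_id", "start_frame", "end_frame")]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("bout matching scores overlap per focal bee", {
  man <- label_intervals(c(1L, 1L, 2L), rep("antennation", 3),
                         c(10L, 40L, 10L), c(20L, 50L, 20L))
  pred <- data.frame(bee_id = c(1L, 1L, 2L),
                     start_frame = c(12L, 39L, 15L),
                     end_frame = c(18L, 41L, 30L))
  rep <- match_bouts(pred, man)
  expect_equal(rep$n_detected, 3)
  expect_equal(rep$detected_pct, 100)
  expect_equal(rep$false_positive_pct, 0)
  # a predicted bout overlapping nothing counts against precision only
  rep2 <- match_bouts(rbind(pred, data.frame(bee_id = 2L, start_frame = 100L,
                                             end_frame = 110L)), man)
  expect_equal(rep2$detected_pct, 100)
  expect_equal(rep2$false_positive_pct, 25)

  # the testing-set scale: 40 of 43 detected is 93 %
  man43 <- label_intervals(rep(1L, 43), rep("antennation", 43),
                           seq(0L, by = 20L, length.out = 43),
                           seq(5L, by = 20L, length.out = 43))
  pred40 <- data.frame(bee_id = 1L,
                       start_frame = seq(0L, by = 20L, length.out = 40),
                       end_frame = seq(5L, by = 20L, length.out = 40))
  r <- match_bouts(pred40, man43)
  expect_equal(r$detected_pct, 93)
  expect_equal(r$false_negative_pct, 7)
  expect_equal(r$exact$detected_pct, 100 * 40 / 43)

  # one predicted bout overlapping two manual bouts detects both, no FP
  two <- label_intervals(c(1L, 1L), c("begging", "begging"),
                         c(0L, 10L), c(4L, 14L))
  one <- data.frame(bee_id = 1L, start_frame = 2L, end_frame = 12L)
  r2 <- match_bouts(one, two)
  expect_equal(r2$n_detected, 2)
  expect_equal(r2$false_positive_pct, 0)

  # same frames on another bee do not match
  r3 <- match_bouts(data.frame(bee_id = 9L, start_frame = 0L, end_frame = 59L),
                    two)
  expect_equal(r3$n_detected, 0)
  expect_equal(r3$false_positive_pct, 100)
})

test_that("adding predicted bouts never lowers the detected percentage", {
  set.seed(23)
  man <- label_intervals(rep(1L, 8), rep("offering", 8),
                         seq(0L, by = 30L, length.out = 8),
                         seq(9L, by = 30L, length.out = 8))
  pred <- data.frame(bee_id = 1L, start_frame = c(2L, 65L),
                     end_frame = c(6L, 70L))
  base <- match_bouts(pred, man)$exact$detected_pct
  for (extra in seq(0, 200, by = 35)) {
    pred2 <- rbind(pred, data.frame(bee_id = 1L, start_frame = extra,
                                    end_frame = extra + 3L))
    expect_gte(match_bouts(pred2, man)$exact$detected_pct, base)
  }
})

test_that("the 5 s duration threshold is inclusive", {
  expect_equal(classify_by_duration(8), "trophallaxis*")
  expect_equal(classify_by_duration(1.8), "non-trophallaxis*")
  expect_equal(classify_by_duration(5.0), "trophallaxis*")
  expect_equal(classify_by_duration(4.75), "non-trophallaxis*")
  expect_error(classify_by_duration(3, threshold_s = 0), "positive")
})

test_that("duration summaries follow the linear-interpolation quantile rule", {
  ds <- duration_summary(rep("begging", 4), c(1, 2, 3, 4))
  expect_equal(ds$median_s, 2.5)
  expect_equal(ds$q75_s, 3.25)
  one <- duration_summary("offering", 3)
  expect_equal(one$n, 1)
  expect_equal(one$rel_pct, 100)
  expect_equal(unlist(one[, c("min_s", "max_s", "median_s", "q75_s")]),
               c(min_s = 3, max_s = 3, median_s = 3, q75_s = 3))
  expect_error(duration_summary(character(), numeric()))
})

test_that("Kruskal-Wallis matches a brute-force rank oracle", {
  # all-constant data carries no rank signal
  kw0 <- kruskal_wallis(rep(7, 9), rep(c("a", "b", "c"), 3))
  expect_equal(kw0$H, 0)
  expect_equal(kw0$df, 2)

  # fully separated small groups, checked against the hand formula
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, brute_kruskal_H(c(1:6), rep(c("a", "b"), each = 3)),
               tolerance = 1e-12)
  expect_equal(kw$df, 1)

  # four classes give three degrees of freedom
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22, 30, 31, 32)
  g <- rep(c("t", "b", "o", "a"), each = 3)
  expect_equal(kruskal_wallis(v, g)$df, 3)
  expect_error(kruskal_wallis(1:3, rep("a", 3)), "2 groups")
})

test_that("Dunn's test matches rank arithmetic and flags identical groups as equal", {
  d0 <- dunn_test(rep(4, 10), rep(c("x", "y"), 5))
  expect_equal(d0$Q, 0)
  expect_equal(d0$p_value, 1)

  v <- c(1, 1, 2, 5, 6, 6, 6, 9, 12, 14)
  g <- c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c")
  dt <- dunn_test(v, g)
  expect_equal(nrow(dt), 3)
  for (i in seq_len(nrow(dt)))
    expect_equal(dt$Q[i], brute_dunn_Q(v, g, dt$group_i[i], dt$group_j[i]),
                 tolerance = 1e-12)

  # four classes yield six pairwise comparisons
  v4 <- rnorm(20); g4 <- rep(c("a", "b", "c", "d"), 5)
  expect_equal(nrow(dunn_test(v4, g4)), 6)
})
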