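#' Segment per-frame predictions into bouts
#'
#' Takes per-(bee, frame) EB/NEB labels (as returned by
#' [predict.stump_ensemble()]) and extracts maximal runs of EB frames per
#' bee. Runs separated by at most `gap_fill` NEB (or missing) frames are
#' merged; merged runs shorter than `min_len` frames are dropped. The
#' bout's partner is the modal closest bee over its frames (when a
#' `closest_id` column is present) and its confidence is the mean score of
#' its EB frames.
#'
#' @param frame_labels data.frame with `bee_id`, `frame`, `label`
#'   (`"EB"`/`"NEB"`), optionally `score` and `closest_id`.
#' @param gap_fill maximum gap (frames) bridged between EB runs.
#' @param min_len minimum bout length in frames.
#' @param fps frames per second, for durations.
#' @return data.frame of class `bout_table`: `bee_id`, `partner_id`,
#'   `start_frame`, `end_frame`, `n_frames`, `duration_s`, `mean_score`.
#' @export
extract_bouts <- function(frame_labels, gap_fill = 2, min_len = 1, fps = 4) {
  stopifnot(gap_fill >= 0, min_len >= 0,
            all(c("bee_id", "frame", "label") %in% names(frame_labels)))
  out <- list()
  for (b in unique(frame_labels$bee_id)) {
    sub <- frame_labels[frame_labels$bee_id == b, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    fr <- sub$frame[sub$label == "EB"]
    if (!length(fr)) next
    # merge EB frames whose gaps are <= gap_fill + 1 apart
    brk <- c(0L, which(diff(fr) > gap_fill + 1L), length(fr))
    for (i in seq_len(length(brk) - 1L)) {
      f0 <- fr[brk[i] + 1L]; f1 <- fr[brk[i + 1L]]
      if (f1 - f0 + 1L < min_len) next
      inb <- sub$frame >= f0 & sub$frame <= f1 & sub$label == "EB"
      partner <- NA_integer_
      if ("closest_id" %in% names(sub)) {
        cp <- sub$closest_id[inb]
        cp <- cp[!is.na(cp)]
        if (length(cp)) {
          tb <- table(cp)
          partner <- as.integer(names(tb)[which.max(tb)])
        }
      }
      ms <- if ("score" %in% names(sub)) mean(sub$score[inb], na.rm = TRUE)
            else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        bee_id = b, partner_id = partner, start_frame = f0, end_frame = f1,
        n_frames = f1 - f0 + 1L, duration_s = (f1 - f0 + 1L) / fps,
        mean_score = ms)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(bee_id = integer(), partner_id = integer(),
               start_frame = integer(), end_frame = integer(),
               n_frames = integer(), duration_s = numeric(),
               mean_score = numeric())
  rownames(res) <- NULL
  class(res) <- c("bout_table", "data.frame")
  res
}

#' Bout-level detection report
#'
#' Compares predicted bouts with manually annotated (or planted) encounter
#' intervals. A manual EB interval counts as detected iff at least one
#' predicted bout of the same focal bee overlaps it by one or more frames
#' (one predicted bout may detect several manual bouts and vice versa). A
#' predicted bout overlapping no manual EB interval of its bee counts as a
#' false positive; the false-positive percentage is taken over the number
#' of predicted bouts. Percentages are reported rounded to integers, with
#' the exact fractions retained.
#'
#' @param predicted a [extract_bouts()] table.
#' @param manual a [label_intervals()] table; only its EB rows are used.
#' @return list of class `bout_match_report`: `n_manual`, `n_predicted`,
#'   `n_detected`, `detected_pct`, `false_negative_pct`,
#'   `false_positive_pct` (integer-rounded) and `exact` (unrounded).
#' @export
match_bouts <- function(predicted, manual) {
  man <- manual[manual$group == "EB", , drop = FALSE]
  n_man <- nrow(man); n_pred <- nrow(predicted)
  detected <- logical(n_man)
  fp <- rep(TRUE, n_pred)
  if (n_man && n_pred) {
    for (i in seq_len(n_man)) {
      ov <- predicted$bee_id == man$bee_id[i] &
        predicted$start_frame <= man$end_frame[i] &
        predicted$end_frame >= man$start_frame[i]
      detected[i] <- any(ov)
      fp[ov] <- FALSE
    }
  }
  det <- if (n_man) 100 * sum(detected) / n_man else NA_real_
  fpp <- if (n_pred) 100 * sum(fp) / n_pred else NA_real_
  structure(list(n_manual = n_man, n_predicted = n_pred,
                 n_detected = sum(detected),
                 detected_pct = round(det),
                 false_negative_pct = round(100 - det),
                 false_positive_pct = round(fpp),
                 exact = list(detected_pct = det,
                              false_negative_pct = 100 - det,
                              false_positive_pct = fpp)),
            class = "bout_match_report")
}

#' @export
print.bout_match_report <- function(x, ...) {
  cat(sprintf("Bout matching: %d/%d manual EBs detected (%d%%), FN %d%%, FP %d%% of %d predicted bouts\n",
              x$n_detected, x$n_manual, x$detected_pct,
              x$false_negative_pct, x$false_positive_pct, x$n_predicted))
  invisible(x)
}

#' Duration-threshold trophallaxis rule
#'
#' Classifies encounter bouts as trophallaxis iff their duration is at
#' least `threshold_s` seconds (boundary inclusive: a 5.0 s bout is
#' trophallaxis at the default threshold). Trophallaxis is the only
#' encounter class whose observed durations (5-30.5 s) sit wholly above
#' the other classes' typical range, which is what makes this simple rule
#' work.
#'
#' @param duration_s numeric vector of bout durations in seconds.
#' @param threshold_s duration threshold, seconds (> 0).
#' @return character vector, `"trophallaxis*"` or `"non-trophallaxis*"`.
#' @export
classify_by_duration <- function(duration_s, threshold_s = 5) {
  if (threshold_s <= 0) stopf("duration threshold must be positive")
  stopifnot(all(duration_s > 0))
  ifelse(duration_s >= threshold_s, "trophallaxis*", "non-trophallaxis*")
}

#' Per-class bout-duration summary
#'
#' Descriptive duration statistics per behaviour class: count, relative
#' proportion (integer-rounded percent of all bouts), and min / max /
#' median / 75th percentile of duration in seconds. Quantiles use linear
#' interpolation between order statistics (`stats::quantile` type 7).
#'
#' @param behavior character vector of class names, one per bout.
#' @param duration_s numeric vector of durations in seconds.
#' @return data.frame of class `duration_stats`: `behavior`, `n`,
#'   `rel_pct`, `min_s`, `max_s`, `median_s`, `q75_s`, ordered by
#'   decreasing count.
#' @export
duration_summary <- function(behavior, duration_s) {
  stopifnot(length(behavior) == length(duration_s), length(behavior) >= 1)
  cls <- unique(behavior)
  rows <- lapply(cls, function(cl) {
    d <- duration_s[behavior == cl]
    data.frame(behavior = cl, n = length(d),
               rel_pct = round(100 * length(d) / length(duration_s)),
               min_s = min(d), max_s = max(d),
               median_s = unname(stats::median(d)),
               q75_s = unname(stats::quantile(d, 0.75, type = 7)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$n), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("duration_stats", "data.frame")
  out
}

#' Kruskal-Wallis one-way ANOVA on ranks
#'
#' Omnibus nonparametric comparison of bout durations across behaviour
#' classes, with the standard tie correction (delegates to
#' [stats::kruskal.test()]); the p-value uses the chi-square approximation
#' with `groups - 1` degrees of freedom.
#'
#' @param values numeric vector of durations.
#' @param groups class membership, same length.
#' @return list with `H`, `df`, `p_value`, `n`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) == 0)) stopf("every group must be non-empty")
  if (length(unique(values)) == 1) {
    # fully tied data carry no rank information: H = 0 by convention
    return(list(H = 0, df = nlevels(groups) - 1L, p_value = 1,
                n = length(values)))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value), n = length(values))
}

#' Dunn's post hoc pairwise comparisons on ranks
#'
#' For every pair of classes computes Dunn's standardized mean-rank
#' difference
#' `Q = |Rbar_i - Rbar_j| / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))`
#' with tie correction `T = sum(t^3 - t) / (12 (N - 1))` over tie groups,
#' and a two-sided normal p-value. No multiplicity adjustment is applied
#' by default (decisions are taken against `alpha` on the unadjusted
#' p-values, as rank-based post hoc output is conventionally reported);
#' any method of [stats::p.adjust()] can be requested instead.
#'
#' @param values numeric vector of durations.
#' @param groups class membership, same length.
#' @param alpha significance level for the `significant` flag.
#' @param p_adjust multiplicity adjustment passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return data.frame with one row per class pair: `group_i`, `group_j`,
#'   `n`, `Q`, `p_value`, `significant`.
#' @export
dunn_test <- function(values, groups, alpha = 0.05, p_adjust = "none") {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) < 2) stopf("need at least 2 groups")
  if (any(table(groups) == 0)) stopf("every group must be non-empty")
  N <- length(values)
  rk <- rank(values)
  mean_rank <- tapply(rk, groups, mean)
  n_g <- tapply(rk, groups, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  res <- lapply(seq_len(ncol(pairs)), function(p) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n_g[[i]] + 1 / n_g[[j]]))
    Q <- if (se > 0) abs(mean_rank[[i]] - mean_rank[[j]]) / se else 0
    data.frame(group_i = i, group_j = j, n = n_g[[i]] + n_g[[j]],
               Q = Q, p_value = 2 * stats::pnorm(-Q))
  })
  out <- do.call(rbind, res)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Frame labels from a bout table
#'
#' Inverse of [extract_bouts()] for round-trip checks and simulation:
#' expands bouts into per-(bee, frame) `"EB"` labels over a frame range,
#' `"NEB"` elsewhere.
#'
#' @param bouts data.frame with `bee_id`, `start_frame`, `end_frame`.
#' @param bee_ids bees to cover.
#' @param frame_range inclusive `c(first, last)` frames to cover.
#' @return data.frame `bee_id`, `frame`, `label`.
#' @export
bouts_to_frame_labels <- function(bouts, bee_ids, frame_range) {
  frames <- frame_range[1]:frame_range[2]
  out <- expand.grid(frame = frames, bee_id = bee_ids,
                     KEEP.OUT.ATTRS = FALSE)[, c("bee_id", "frame")]
  out$label <- "NEB"
  for (i in seq_len(nrow(bouts))) {
    sel <- out$bee_id == bouts$bee_id[i] &
      out$frame >= bouts$start_frame[i] & out$frame <= bouts$end_frame[i]
    out$label[sel] <- "EB"
  }
  out
}
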