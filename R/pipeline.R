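#' Pipeline configuration
#'
#' Bundles every tunable parameter of the simulate - featurize - train -
#' predict - evaluate - duration-classify pipeline with its default.
#' Configurations round-trip through YAML via [read_config()] /
#' [write_config()]. The single `seed` is split deterministically into
#' per-stage substreams so each stage is reproducible in isolation.
#'
#' @param n_bees,duration_s simulation size.
#' @param fps frames per second.
#' @param arena comb `c(width, height)` in mm.
#' @param encounter_rate planted bouts per bee-hour.
#' @param class_mix named encounter-class proportions (must sum to 1).
#' @param use_dropout apply state-dependent detection dropout to the
#'   simulated tracking before feature computation.
#' @param body_length worker body length, mm.
#' @param neighbor_radius neighbour-count radius, mm.
#' @param max_head_dist,max_facing head-to-head predicate thresholds
#'   (mm, degrees).
#' @param window_radii window radii in frames for feature statistics.
#' @param boost_rounds boosting rounds for the classifier.
#' @param cv_folds,cv_rounds cross-validation folds and re-split rounds.
#' @param gap_fill,min_len bout post-processing (frames).
#' @param duration_threshold_s trophallaxis duration threshold, seconds.
#' @param train_fraction fraction of planted bouts used for training.
#' @param max_neb_intervals cap on NEB intervals entering training.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_bees = 10, duration_s = 300, fps = 4,
                            arena = c(370, 200), encounter_rate = 3.76,
                            class_mix = c(antennation = 0.57, offering = 0.26,
                                          begging = 0.09, trophallaxis = 0.08),
                            use_dropout = FALSE, body_length = 13,
                            neighbor_radius = 30, max_head_dist = 4.5,
                            max_facing = 25, window_radii = c(1, 2, 4),
                            boost_rounds = 100, cv_folds = 10, cv_rounds = 10,
                            gap_fill = 2, min_len = 1,
                            duration_threshold_s = 5, train_fraction = 0.5,
                            max_neb_intervals = 200, seed = 1) {
  cfg <- as.list(environment())
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config()
  unknown <- setdiff(names(raw), names(base))
  if (length(unknown)) stopf("unknown config field: %s", unknown[1])
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (nm == "class_mix") v <- unlist(v)
    base[[nm]] <- v
  }
  base
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$class_mix <- as.list(cfg$class_mix)  # keep names through YAML maps
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# Deterministic, seeded split of planted bouts into train/test halves.
split_bouts <- function(bouts, train_fraction, seed) {
  n <- nrow(bouts)
  n_train <- max(1L, floor(n * train_fraction))
  idx <- with_seed(seed, sample(n))
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[-seq_len(n_train)]))
}

#' Run the full annotation pipeline on simulated data
#'
#' Executes all stages in order: simulate a colony; optionally degrade
#' detections; compute per-frame and windowed features; split the planted
#' encounter bouts into training and held-out halves; train the encounter
#' classifier on the training-half EB intervals plus a capped, seeded
#' sample of NEB intervals; score every frame; segment predictions into
#' bouts; match them against the held-out planted encounters; apply the
#' duration-threshold trophallaxis rule; and summarise planted bout
#' durations with the rank-based statistics. Intermediate artifacts
#' (tracking, labels, features, model, scores, bouts) are written to
#' `workdir`; the returned report (also written as `report.json`) carries
#' the cross-validation estimates, the bout-detection report, the
#' duration summary with omnibus and pairwise rank tests, and the
#' duration-rule table. Identical config and seed give byte-identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @param workdir writable output directory (created if needed).
#' @param verbose print stage progress and timings.
#' @return the report, invisibly a list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), workdir = tempdir(),
                         verbose = FALSE) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] done in %.1f s", stage,
                    as.numeric(Sys.time()) - t0))
  stage_seed <- function(stage) derive_seed(config$seed, stage)
  report <- list(config = unclass(config), warnings = character())

  t0 <- as.numeric(Sys.time())
  sim <- simulate_colony(config$n_bees, config$duration_s,
                         seed = stage_seed("simulate"),
                         encounter_rate = config$encounter_rate,
                         class_mix = config$class_mix, fps = config$fps,
                         arena = config$arena,
                         body_length = config$body_length)
  write_tracking(sim$tracking, file.path(workdir, "tracks.csv"))
  write_labels(sim$labels, file.path(workdir, "labels.csv"))
  say("simulate", t0)

  tracking <- sim$tracking
  if (isTRUE(config$use_dropout)) {
    tracking <- degrade_detections(tracking, sim$states,
                                   seed = stage_seed("dropout"))
    write_tracking(tracking, file.path(workdir, "tracks_degraded.csv"))
  }

  t0 <- as.numeric(Sys.time())
  pf <- compute_per_frame(tracking, body_length = config$body_length,
                          neighbor_radius = config$neighbor_radius)
  wf <- compute_window_features(pf, radii = config$window_radii)
  # full feature tables get large; persist them only at moderate sizes
  if (nrow(wf) <= 50000)
    write_features(wf, file.path(workdir, "features.csv"))
  say("featurize", t0)

  bouts <- sim$bouts
  report$n_planted_bouts <- nrow(bouts)
  if (nrow(bouts) == 0) {
    warning("no planted encounter bouts (single bee or zero rate); classifier stages skipped")
    report$warnings <- c(report$warnings, "no planted encounter bouts; classifier stages skipped")
    report$bout_detection <- list(n_manual = 0, n_predicted = 0,
                                  detected_pct = NA, false_positive_pct = NA)
    report$cross_validation <- NULL
    report$duration_summary <- NULL
    report$duration_rule <- NULL
    class(report) <- c("pipeline_report", "list")
    jsonlite::write_json(unclass(report), file.path(workdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    return(invisible(report))
  }

  sp <- split_bouts(bouts, config$train_fraction, stage_seed("split"))
  eb_lab <- function(idx) label_intervals(
    bee_id = c(bouts$bee_a[idx], bouts$bee_b[idx]),
    behavior = rep(bouts$behavior[idx], 2),
    start_frame = rep(bouts$start_frame[idx], 2),
    end_frame = rep(bouts$end_frame[idx], 2),
    partner_id = c(bouts$bee_b[idx], bouts$bee_a[idx]))
  train_eb <- eb_lab(sp$train)
  test_eb <- eb_lab(sp$test)
  neb_all <- sim$labels[sim$labels$group == "NEB", , drop = FALSE]
  n_neb <- min(nrow(neb_all), config$max_neb_intervals)
  neb_keep <- with_seed(stage_seed("neb"), sort(sample(nrow(neb_all), n_neb)))
  train_lab <- rbind(train_eb, neb_all[neb_keep, , drop = FALSE])
  class(train_lab) <- c("label_intervals", "data.frame")

  t0 <- as.numeric(Sys.time())
  model <- train_encounter_classifier(wf, train_lab,
                                      n_rounds = config$boost_rounds,
                                      seed = stage_seed("train"))
  write_model(model, file.path(workdir, "model.json"))
  say("train", t0)

  t0 <- as.numeric(Sys.time())
  scores <- predict(model, wf)
  utils::write.csv(scores, file.path(workdir, "scores.csv"),
                   row.names = FALSE)
  pred_bouts <- extract_bouts(scores, gap_fill = config$gap_fill,
                              min_len = config$min_len, fps = config$fps)
  utils::write.csv(as.data.frame(pred_bouts),
                   file.path(workdir, "bouts.csv"), row.names = FALSE)
  say("predict", t0)

  t0 <- as.numeric(Sys.time())
  match <- match_bouts(pred_bouts, test_eb)
  k <- min(config$cv_folds, nrow(train_eb),
           sum(train_lab$group == "NEB"))
  cv <- if (k >= 2 && config$cv_rounds >= 1) {
    cv_est <- cross_validate(wf, train_lab, k = k,
                             n_rounds = config$cv_rounds,
                             boost_rounds = config$boost_rounds,
                             seed = stage_seed("cv"))
    list(mean = cv_est$mean, sd = cv_est$sd, k = cv_est$k,
         n_rounds = cv_est$n_rounds)
  } else NULL
  say("evaluate", t0)

  ds <- duration_summary(bouts$behavior, bouts$duration_s)
  multi_class <- length(unique(bouts$behavior)) >= 2
  kw <- if (multi_class) kruskal_wallis(bouts$duration_s, bouts$behavior)
        else NULL
  dn <- if (multi_class) dunn_test(bouts$duration_s, bouts$behavior)
        else NULL
  rule <- classify_by_duration(pred_bouts$duration_s,
                               config$duration_threshold_s)
  planted_rule <- classify_by_duration(bouts$duration_s,
                                       config$duration_threshold_s)
  troph <- bouts$behavior == "trophallaxis"
  report$cross_validation <- cv
  report$bout_detection <- unclass(match)
  report$duration_summary <- as.data.frame(ds)
  report$rank_tests <- list(kruskal_wallis = kw, dunn = dn)
  report$duration_rule <- list(
    threshold_s = config$duration_threshold_s,
    planted_trophallaxis_classified_pct =
      if (any(troph)) 100 * mean(planted_rule[troph] == "trophallaxis*")
      else NA,
    planted_non_trophallaxis_false_pct =
      if (any(!troph)) 100 * mean(planted_rule[!troph] == "trophallaxis*")
      else NA,
    predicted_bouts_trophallaxis_pct =
      if (nrow(pred_bouts)) 100 * mean(rule == "trophallaxis*") else NA)
  class(report) <- c("pipeline_report", "list")
  jsonlite::write_json(unclass(report), file.path(workdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  planted bouts: %d\n", x$n_planted_bouts))
  if (!is.null(x$bout_detection$detected_pct) &&
      !is.na(x$bout_detection$detected_pct))
    cat(sprintf("  held-out bout detection: %s%% (FP %s%%)\n",
                x$bout_detection$detected_pct,
                x$bout_detection$false_positive_pct))
  if (!is.null(x$cross_validation))
    cat(sprintf("  cross-validation EB/NEB diagonal: %.1f%% / %.1f%%\n",
                x$cross_validation$mean[1, 1], x$cross_validation$mean[2, 2]))
  if (!is.null(x$rank_tests$kruskal_wallis))
    cat(sprintf("  Kruskal-Wallis: H = %.1f, df = %d, p = %.3g\n",
                x$rank_tests$kruskal_wallis$H, x$rank_tests$kruskal_wallis$df,
                x$rank_tests$kruskal_wallis$p_value))
  invisible(x)
}
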