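# Gentle boosting over depth-1 decision stumps: the classifier core used to
# score each (bee, frame) as encounter (EB) vs non-encounter (NEB).

# Expand label intervals into per-frame keys and +/-1 targets, matched
# against the rows of a feature table. Returns row indices and y.
labelled_frames <- function(features, labels) {
  n <- vapply(seq_len(nrow(labels)),
              function(i) labels$end_frame[i] - labels$start_frame[i] + 1L, 0L)
  bee <- rep(labels$bee_id, n)
  grp <- rep(labels$group, n)
  frame <- unlist(lapply(seq_len(nrow(labels)), function(i)
    labels$start_frame[i]:labels$end_frame[i]))
  interval <- rep(seq_len(nrow(labels)), n)
  key <- paste(bee, frame)
  dup <- duplicated(key)
  key <- key[!dup]; grp <- grp[!dup]; interval <- interval[!dup]
  fkey <- paste(features$bee_id, features$frame)
  row <- match(key, fkey)
  ok <- !is.na(row)
  list(row = row[ok], y = ifelse(grp[ok] == "EB", 1, -1),
       interval = interval[ok])
}

fit_gentle_boost <- function(X, y, w, n_rounds) {
  n <- nrow(X); p <- ncol(X)
  ords <- lapply(seq_len(p), function(j) order(X[, j]))
  stumps <- vector("list", n_rounds)
  eps <- 1e-12
  for (m in seq_len(n_rounds)) {
    best <- list(crit = -Inf, feature = 1L, threshold = -Inf,
                 out_le = 0, out_gt = 0)
    totw <- sum(w); totwy <- sum(w * y)
    # "no split": constant weighted-mean stump (handles degenerate features)
    const <- totwy / totw
    best$crit <- totwy^2 / totw
    best$out_le <- const; best$out_gt <- const
    for (j in seq_len(p)) {
      o <- ords[[j]]
      xs <- X[o, j]
      cw <- cumsum(w[o]); cwy <- cumsum(w[o] * y[o])
      cut <- which(diff(xs) > 0)         # split between distinct values
      if (!length(cut)) next
      wl <- cw[cut]; wyl <- cwy[cut]
      wr <- totw - wl; wyr <- totwy - wyl
      crit <- wyl^2 / pmax(wl, eps) + wyr^2 / pmax(wr, eps)
      i <- which.max(crit)
      if (crit[i] > best$crit + eps) {
        ci <- cut[i]
        best <- list(crit = crit[i], feature = j,
                     threshold = (xs[ci] + xs[ci + 1]) / 2,
                     out_le = wyl[i] / max(wl[i], eps),
                     out_gt = wyr[i] / max(wr[i], eps))
      }
    }
    fm <- ifelse(X[, best$feature] <= best$threshold, best$out_le, best$out_gt)
    w <- w * exp(-y * fm)
    w <- w / sum(w)
    stumps[[m]] <- best[c("feature", "threshold", "out_le", "out_gt")]
  }
  stumps
}

#' Train the encounter classifier
#'
#' Fits a gentle-boosting ensemble of depth-1 decision stumps on the
#' labelled frames of a windowed feature table. Classes are weight-balanced
#' (EB and NEB frames each contribute half of the initial total weight);
#' each boosting round adds the weighted-least-squares-optimal stump over
#' all feature columns and reweights frames by `exp(-y * f(x))`. The
#' ensemble scores a frame as the sum of its stump outputs; frames with
#' score strictly greater than zero are labelled EB (ties go to NEB, the
#' conservative choice for the rarer positive class). Frames inside no
#' labelled interval, and labelled frames with missing feature values, are
#' excluded from training.
#'
#' @param features a [compute_window_features()] table.
#' @param labels a [label_intervals()] table with both EB and NEB
#'   intervals.
#' @param n_rounds number of boosting rounds (stumps).
#' @param seed integer seed (training is deterministic given data and
#'   seed).
#' @return an object of class `stump_ensemble` with elements `stumps`
#'   (data.frame: `feature`, `threshold`, `out_le`, `out_gt`), `channels`,
#'   `n_rounds`, `seed`, `train_error` (frame-wise weighted-balanced
#'   training error).
#' @export
train_encounter_classifier <- function(features, labels, n_rounds = 100,
                                       seed = 1) {
  stopifnot(inherits(features, "data.frame"), n_rounds >= 0)
  channels <- attr(features, "channels")
  if (is.null(channels))
    channels <- setdiff(names(features), c("bee_id", "frame", "closest_id"))
  lf <- labelled_frames(features, labels)
  if (!length(lf$row)) stopf("no labelled frames match the feature table")
  X <- as.matrix(as.data.frame(features)[lf$row, channels, drop = FALSE])
  y <- lf$y
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2)
    stopf("training requires labelled frames from both classes (EB and NEB)")
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  w <- ifelse(y > 0, 0.5 / n_pos, 0.5 / n_neg)
  stumps <- with_seed(seed, fit_gentle_boost(X, y, w, n_rounds))
  sdf <- if (n_rounds > 0) data.frame(
    feature = channels[vapply(stumps, `[[`, 0L, "feature")],
    threshold = vapply(stumps, `[[`, 0, "threshold"),
    out_le = vapply(stumps, `[[`, 0, "out_le"),
    out_gt = vapply(stumps, `[[`, 0, "out_gt"))
  else data.frame(feature = character(), threshold = numeric(),
                  out_le = numeric(), out_gt = numeric())
  model <- structure(list(stumps = sdf, channels = channels,
                          n_rounds = n_rounds, seed = seed),
                     class = "stump_ensemble")
  sc <- ensemble_scores(model, X)
  model$train_error <- sum(ifelse(y > 0, 0.5 / n_pos, 0.5 / n_neg) *
                             ((sc > 0) != (y > 0)))
  model
}

# Raw ensemble scores for a numeric feature matrix (columns = channels).
ensemble_scores <- function(model, X) {
  score <- numeric(nrow(X))
  if (!nrow(model$stumps)) return(score)
  fidx <- match(model$stumps$feature, colnames(X))
  for (m in seq_len(nrow(model$stumps))) {
    score <- score + ifelse(X[, fidx[m]] <= model$stumps$threshold[m],
                            model$stumps$out_le[m], model$stumps$out_gt[m])
  }
  score
}

#' @export
print.stump_ensemble <- function(x, ...) {
  cat(sprintf("Gentle-boosting encounter classifier: %d stumps over %d feature channels\n",
              nrow(x$stumps), length(x$channels)))
  if (!is.null(x$train_error))
    cat(sprintf("Balanced training error: %.3f\n", x$train_error))
  invisible(x)
}

#' @export
summary.stump_ensemble <- function(object, ...) {
  use <- sort(table(object$stumps$feature), decreasing = TRUE)
  cat(sprintf("Stump ensemble: %d rounds, %d distinct features used\n",
              nrow(object$stumps), length(use)))
  if (length(use)) {
    cat("Most-used feature channels:\n")
    print(utils::head(use, 10))
  }
  invisible(list(n_rounds = nrow(object$stumps), feature_usage = use,
                 train_error = object$train_error))
}

#' @export
coef.stump_ensemble <- function(object, ...) object$stumps

#' Score frames with a trained encounter classifier
#'
#' Computes the ensemble score for every row of a feature table and labels
#' frames `EB` iff the score is strictly positive. Frames with missing
#' values in any feature channel used by the model get an `NA` score and
#' the `NEB` label.
#'
#' @param object a [train_encounter_classifier()] model.
#' @param features a feature table with the channels the model was trained
#'   on.
#' @param ... unused.
#' @return data.frame with `bee_id`, `frame`, `closest_id` (if present),
#'   `score`, `label` (`"EB"`/`"NEB"`).
#' @export
predict.stump_ensemble <- function(object, features, ...) {
  have <- if (!is.null(attr(features, "channels"))) attr(features, "channels")
          else names(features)
  missing_ch <- setdiff(object$channels, have)
  if (length(missing_ch))
    stopf("feature table lacks channel '%s' required by the model",
          missing_ch[1])
  used <- unique(object$stumps$feature)
  X <- as.matrix(as.data.frame(features)[, object$channels, drop = FALSE])
  score <- ensemble_scores(object, X)
  if (length(used)) {
    bad <- !stats::complete.cases(X[, used, drop = FALSE])
    score[bad] <- NA_real_
  }
  out <- data.frame(bee_id = features$bee_id, frame = features$frame,
                    score = score,
                    label = ifelse(!is.na(score) & score > 0, "EB", "NEB"))
  if ("closest_id" %in% names(features)) out$closest_id <- features$closest_id
  out
}

#' Serialise / restore a trained classifier
#'
#' The ensemble is stored as documented JSON (channels, rounds, seed and
#' the stump list); a reloaded model produces identical scores.
#'
#' @param model a `stump_ensemble`.
#' @param path file path for the JSON model.
#' @return `read_model` returns the `stump_ensemble`.
#' @export
write_model <- function(model, path) {
  obj <- list(type = "stump_ensemble",
              channels = model$channels,
              n_rounds = model$n_rounds,
              seed = model$seed,
              train_error = model$train_error,
              stumps = model$stumps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$type, "stump_ensemble"))
    stopf("'%s' is not a serialised stump_ensemble", path)
  stumps <- as.data.frame(obj$stumps)
  if (!nrow(stumps)) stumps <- data.frame(feature = character(),
                                          threshold = numeric(),
                                          out_le = numeric(),
                                          out_gt = numeric())
  structure(list(stumps = stumps, channels = obj$channels,
                 n_rounds = obj$n_rounds, seed = obj$seed,
                 train_error = obj$train_error),
            class = "stump_ensemble")
}

#' Bout-wise cross-validation of the encounter classifier
#'
#' Repeats `n_rounds` independent random splits of the labelled intervals
#' into `k` folds, stratified by class (EB/NEB) and drawn over whole
#' intervals so no bout's frames leak across a split. Per round, each fold
#' is held out in turn, the classifier is retrained on the remaining
#' intervals, held-out frames are scored, and the frame-wise confusion
#' percentages (rows: manual EB/NEB; columns: predicted EB*/NEB*; each row
#' summing to 100) are pooled over all held-out frames of the round.
#' Returns the mean and SD of the four percentages across rounds.
#'
#' @param features a windowed feature table.
#' @param labels a [label_intervals()] table.
#' @param k number of folds (>= 2, at most the per-class interval count).
#' @param n_rounds number of independent re-split rounds.
#' @param boost_rounds boosting rounds per fit.
#' @param seed integer seed.
#' @return object of class `cv_estimates`: list with 2x2 matrices `mean`
#'   and `sd` (rows `EB`, `NEB`; columns `EB*`, `NEB*`), `k`, `n_rounds`.
#' @export
cross_validate <- function(features, labels, k = 10, n_rounds = 10,
                           boost_rounds = 100, seed = 1) {
  stopifnot(k >= 2, n_rounds >= 1)
  eb_idx <- which(labels$group == "EB")
  neb_idx <- which(labels$group == "NEB")
  if (!length(eb_idx) || !length(neb_idx))
    stopf("cross-validation needs intervals of both classes")
  if (k > length(eb_idx) || k > length(neb_idx))
    stopf("k = %d exceeds the interval count of a class (EB %d, NEB %d)",
          k, length(eb_idx), length(neb_idx))
  lf <- labelled_frames(features, labels)
  rounds <- with_seed(seed, {
    lapply(seq_len(n_rounds), function(r) {
      fold_of <- integer(nrow(labels))
      fold_of[eb_idx] <- sample(rep_len(seq_len(k), length(eb_idx)))
      fold_of[neb_idx] <- sample(rep_len(seq_len(k), length(neb_idx)))
      conf <- matrix(0, 2, 2)
      for (fold in seq_len(k)) {
        train_lab <- labels[fold_of != fold, , drop = FALSE]
        class(train_lab) <- c("label_intervals", "data.frame")
        model <- train_encounter_classifier(features, train_lab,
                                            n_rounds = boost_rounds,
                                            seed = seed + 1000L * r + fold)
        held <- lf$interval %in% which(fold_of == fold)
        if (!any(held)) next
        rows <- lf$row[held]
        pr <- predict(model, features[rows, , drop = FALSE])
        truth <- ifelse(lf$y[held] > 0, 1L, 2L)      # 1 EB, 2 NEB
        pred <- ifelse(pr$label == "EB", 1L, 2L)
        for (i in 1:2) for (j in 1:2)
          conf[i, j] <- conf[i, j] + sum(truth == i & pred == j)
      }
      sweep(conf, 1, pmax(rowSums(conf), 1), "/") * 100
    })
  })
  arr <- simplify2array(rounds)
  est <- structure(list(mean = apply(arr, 1:2, mean),
                        sd = apply(arr, 1:2, stats::sd),
                        k = k, n_rounds = n_rounds),
                   class = "cv_estimates")
  dimnames(est$mean) <- dimnames(est$sd) <-
    list(manual = c("EB", "NEB"), predicted = c("EB*", "NEB*"))
  est
}

#' @export
print.cv_estimates <- function(x, ...) {
  cat(sprintf("Cross-validation: %d folds, %d rounds (frame-wise %%, mean +/- SD)\n",
              x$k, x$n_rounds))
  m <- matrix(sprintf("%.1f (+/-%.1f)", x$mean, x$sd), 2, 2,
              dimnames = dimnames(x$mean))
  print(m, quote = FALSE)
  invisible(x)
}
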