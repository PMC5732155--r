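#' Tracking datasets for barcode-tagged bees
#'
#' A `tracking_dataset` holds per-frame detections of 2D-barcode-tagged bees:
#' one row per detection with the tag identity, frame number, UNIX timestamp
#' (0.01 s resolution), comb-plane coordinates in millimetres and body
#' orientation in degrees. Rows are stored sorted by `bee_id` then `frame`;
#' missing detections are absent rows, never sentinel values.
#'
#' Coordinate conventions: origin at the top-left of the comb image, x
#' rightward, y downward, millimetres; frames are 0-based; orientation is in
#' degrees in `[0, 360)` with 0 along +x, counter-clockwise positive.
#'
#' @param records data.frame with columns `bee_id`, `frame`, `time`, `x`,
#'   `y`, `orientation` (a logical `synthetic` column marking interpolated
#'   rows is optional and preserved).
#' @param fps frames per second of the recording (default 4).
#' @param arena numeric length-2, comb width and height in mm. Default
#'   `c(370, 200)`, one side of a standard one-frame observation comb.
#' @param validate check invariants (orientation range, unique keys,
#'   positions inside the arena, time non-decreasing per bee).
#' @return an object of class `tracking_dataset`: the records data.frame
#'   with attributes `fps`, `arena` and `frame_range`.
#' @export
tracking_dataset <- function(records, fps = 4, arena = c(370, 200),
                             validate = TRUE) {
  req <- c("bee_id", "frame", "time", "x", "y", "orientation")
  if (missing(records) || is.null(records)) {
    records <- data.frame(bee_id = integer(), frame = integer(),
                          time = numeric(), x = numeric(), y = numeric(),
                          orientation = numeric())
  }
  miss <- setdiff(req, names(records))
  if (length(miss))
    stopf("tracking records lack column(s): %s", paste(miss, collapse = ", "))
  records <- records[, c(req, intersect("synthetic", names(records))), drop = FALSE]
  records$bee_id <- as.integer(records$bee_id)
  records$frame <- as.integer(records$frame)
  if (!"synthetic" %in% names(records))
    records$synthetic <- rep(FALSE, nrow(records))
  ord <- order(records$bee_id, records$frame)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL

  if (validate && nrow(records)) {
    if (anyNA(records[req]))
      stopf("tracking records contain missing values")
    if (any(records$frame < 0))
      stopf("frame numbers must be >= 0")
    bad <- which(records$orientation < 0 | records$orientation >= 360)
    if (length(bad))
      stopf("orientation outside [0, 360) in %d record(s), first at row %d",
            length(bad), bad[1])
    key <- paste(records$bee_id, records$frame)
    if (anyDuplicated(key))
      stopf("duplicate (bee_id, frame) pair: %s",
            key[which(duplicated(key))[1]])
    out <- records$x < 0 | records$x > arena[1] |
      records$y < 0 | records$y > arena[2]
    if (any(out))
      stopf("%d record(s) lie outside the %g x %g mm arena",
            sum(out), arena[1], arena[2])
    # frames strictly increasing per bee is implied by sorted unique keys;
    # check time monotone with frame within bee
    dt <- diff(records$time)
    same_bee <- diff(records$bee_id) == 0
    if (any(same_bee & dt < 0))
      stopf("time decreases with frame for bee %d",
            records$bee_id[which(same_bee & dt < 0)[1]])
  }

  structure(records,
            fps = fps,
            arena = as.numeric(arena),
            frame_range = if (nrow(records)) range(records$frame) else integer(),
            class = c("tracking_dataset", "data.frame"))
}

#' @export
print.tracking_dataset <- function(x, ...) {
  fr <- attr(x, "frame_range")
  cat(sprintf("Tracking dataset: %d detections, %d bees, frames [%s], %g fps, arena %g x %g mm\n",
              nrow(x), length(unique(x$bee_id)),
              if (length(fr)) paste(fr, collapse = ", ") else "",
              attr(x, "fps"), attr(x, "arena")[1], attr(x, "arena")[2]))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Read a tracking table
#'
#' Reads a delimited tracking table (comma by default, tab accepted and
#' auto-detected from the header line) with columns
#' `bee_id,frame,time,x,y,orientation` into a validated [tracking_dataset()].
#'
#' @param path file path.
#' @inheritParams tracking_dataset
#' @return a `tracking_dataset`.
#' @export
read_tracking <- function(path, fps = 4, arena = c(370, 200)) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE),
    error = function(e) stopf("malformed tracking table '%s': %s", path,
                              conditionMessage(e)))
  req <- c("bee_id", "frame", "time", "x", "y", "orientation")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("tracking table '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  for (col in req) {
    v <- df[[col]]
    if (is.character(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v))
        stopf("malformed value in column '%s' at line %d of %s",
              col, which(is.na(vn))[1] + 1L, path)
      df[[col]] <- vn
    }
  }
  if ("synthetic" %in% names(df)) df$synthetic <- as.logical(df$synthetic)
  tracking_dataset(df, fps = fps, arena = arena)
}

#' Write a tracking table
#'
#' Writes the six record columns as delimited text, one row per detection in
#' (bee, frame) order. Times keep their 0.01 s precision, coordinates are
#' written at 0.001 mm and orientations at 0.001 degrees, so datasets whose
#' values lie on those grids (all datasets produced by this package)
#' round-trip exactly through [read_tracking()].
#'
#' @param dataset a [tracking_dataset()].
#' @param path output file path.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(dataset, path, sep = ",") {
  stopifnot(inherits(dataset, "tracking_dataset"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stopf("cannot open '%s' for writing: %s", path, conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(c("bee_id", "frame", "time", "x", "y", "orientation"),
                   collapse = sep), con)
  if (nrow(dataset)) {
    lines <- paste(dataset$bee_id, dataset$frame,
                   sprintf("%.2f", dataset$time),
                   sprintf("%.3f", dataset$x),
                   sprintf("%.3f", dataset$y),
                   sprintf("%.3f", dataset$orientation),
                   sep = sep)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Fill short per-bee detection gaps by interpolation
#'
#' Missed detections shorter than or equal to `max_gap` frames are filled
#' with linearly interpolated position and time and shortest-arc circular
#' interpolation of orientation. Longer gaps are left untouched. Inserted
#' records carry `synthetic = TRUE`; existing records are never modified.
#' Off by default in the pipeline: the upstream tracker's own postprocessing
#' is unspecified, so interpolation is an explicit, opt-in stand-in.
#'
#' @param dataset a [tracking_dataset()].
#' @param max_gap maximum number of consecutive missing frames to fill
#'   (`0` = no-op).
#' @return a `tracking_dataset` including the interpolated records.
#' @export
interpolate_gaps <- function(dataset, max_gap) {
  stopifnot(inherits(dataset, "tracking_dataset"), max_gap >= 0)
  if (max_gap == 0 || nrow(dataset) == 0) return(dataset)
  pieces <- list(as.data.frame(dataset))
  for (b in unique(dataset$bee_id)) {
    tr <- dataset[dataset$bee_id == b, , drop = FALSE]
    if (nrow(tr) < 2) next
    gaps <- diff(tr$frame) - 1L
    idx <- which(gaps >= 1L & gaps <= max_gap)
    for (i in idx) {
      g <- gaps[i]
      tfrac <- seq_len(g) / (g + 1)
      dphi <- angle_diff_signed(tr$orientation[i + 1], tr$orientation[i])
      pieces[[length(pieces) + 1L]] <- data.frame(
        bee_id = b,
        frame = tr$frame[i] + seq_len(g),
        time = round(tr$time[i] + tfrac * (tr$time[i + 1] - tr$time[i]), 2),
        x = round(tr$x[i] + tfrac * (tr$x[i + 1] - tr$x[i]), 3),
        y = round(tr$y[i] + tfrac * (tr$y[i + 1] - tr$y[i]), 3),
        orientation = round(wrap360(tr$orientation[i] + tfrac * dphi), 3),
        synthetic = TRUE)
    }
  }
  tracking_dataset(do.call(rbind, pieces), fps = attr(dataset, "fps"),
                   arena = attr(dataset, "arena"))
}

#' Tag detection rate over a frame window
#'
#' Percentage of frames within `window` (inclusive bounds) in which the
#' given bee's tag was detected.
#'
#' @param dataset a [tracking_dataset()].
#' @param bee_id tag identity; must occur in the dataset.
#' @param window integer length-2, `c(first, last)` frame, inclusive.
#' @return percentage in `[0, 100]`.
#' @export
detection_rate <- function(dataset, bee_id, window) {
  stopifnot(inherits(dataset, "tracking_dataset"), length(window) == 2)
  if (window[2] < window[1]) stopf("empty window")
  if (!bee_id %in% dataset$bee_id) stopf("unknown bee_id: %s", bee_id)
  fr <- dataset$frame[dataset$bee_id == bee_id]
  n_det <- sum(fr >= window[1] & fr <= window[2])
  100 * n_det / (window[2] - window[1] + 1)
}

#' Per-frame movement statistics
#'
#' Mean and SD of displacement (mm) and absolute orientation change
#' (degrees, wrapped to `[0, 180]`) over all consecutive-frame detection
#' pairs of all bees. These are the statistics used to verify that a 4 fps
#' recording rate captures bee movement with adequate temporal resolution.
#'
#' @param dataset a [tracking_dataset()].
#' @return list with `mean_step`, `sd_step`, `mean_dori`, `sd_dori`
#'   (per-frame units) and `n_steps`.
#' @export
frame_step_stats <- function(dataset) {
  stopifnot(inherits(dataset, "tracking_dataset"))
  same_bee <- diff(dataset$bee_id) == 0
  consec <- same_bee & diff(dataset$frame) == 1L
  if (!any(consec)) stopf("no consecutive-frame detection pairs in dataset")
  i <- which(consec)
  dx <- dataset$x[i + 1] - dataset$x[i]
  dy <- dataset$y[i + 1] - dataset$y[i]
  step <- sqrt(dx^2 + dy^2)
  dori <- angle_diff_abs(dataset$orientation[i + 1], dataset$orientation[i])
  list(mean_step = mean(step), sd_step = stats::sd(step),
       mean_dori = mean(dori), sd_dori = stats::sd(dori),
       n_steps = length(step))
}
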