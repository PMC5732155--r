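#' Behaviour label intervals
#'
#' A `label_intervals` table holds manually annotated (or planted) behaviour
#' bouts: one row per (focal bee, behaviour episode) with inclusive frame
#' bounds. Behaviours split into two groups: encounter behaviours (EB) --
#' antennation, begging, offering, trophallaxis -- in which two workers face
#' head to head with antennal contact, and non-encounter behaviours (NEB) --
#' sitting, walking, self-grooming, social grooming, sitting then walking.
#'
#' @param bee_id integer focal bee identities.
#' @param behavior character, one of [eb_classes()] or [neb_classes()].
#' @param start_frame,end_frame inclusive frame bounds, `start <= end`.
#' @param partner_id integer partner identities, `NA` where no partner.
#' @return data.frame of class `label_intervals` with columns `bee_id`,
#'   `partner_id`, `behavior`, `group` (`"EB"`/`"NEB"`), `start_frame`,
#'   `end_frame`.
#' @export
label_intervals <- function(bee_id, behavior, start_frame, end_frame,
                            partner_id = NA_integer_) {
  n <- length(bee_id)
  df <- data.frame(bee_id = as.integer(bee_id),
                   partner_id = rep_len(as.integer(partner_id), n),
                   behavior = as.character(behavior),
                   start_frame = as.integer(start_frame),
                   end_frame = as.integer(end_frame))
  bad <- setdiff(df$behavior, c(eb_classes(), neb_classes()))
  if (length(bad)) stopf("unknown behaviour class: %s", bad[1])
  if (any(df$start_frame > df$end_frame))
    stopf("start_frame > end_frame in %d interval(s)",
          sum(df$start_frame > df$end_frame))
  df$group <- behavior_group(df$behavior)
  df <- df[, c("bee_id", "partner_id", "behavior", "group",
               "start_frame", "end_frame")]
  class(df) <- c("label_intervals", "data.frame")
  df
}

#' Behaviour class vocabularies
#'
#' `eb_classes()` lists the four encounter-behaviour classes grouped as a
#' single positive class for classification; `neb_classes()` the
#' non-encounter classes; `behavior_group()` maps a behaviour name to
#' `"EB"` or `"NEB"`.
#'
#' @return character vectors; for `behavior_group`, `"EB"` or `"NEB"` per
#'   element.
#' @export
eb_classes <- function() c("antennation", "begging", "offering", "trophallaxis")

#' @rdname eb_classes
#' @export
neb_classes <- function() c("sitting", "walking", "self_grooming",
                            "social_grooming", "sitting_then_walking")

#' @rdname eb_classes
#' @param behavior character vector of behaviour names.
#' @export
behavior_group <- function(behavior) {
  out <- ifelse(behavior %in% eb_classes(), "EB",
                ifelse(behavior %in% neb_classes(), "NEB", NA_character_))
  if (anyNA(out)) stopf("unknown behaviour class: %s", behavior[is.na(out)][1])
  out
}

#' Interval duration in seconds
#'
#' Inclusive frame intervals at `fps` frames per second:
#' `(end - start + 1) / fps`.
#'
#' @param intervals a [label_intervals()] table (or any data.frame with
#'   `start_frame`, `end_frame`).
#' @param fps frames per second.
#' @return numeric vector of durations in seconds.
#' @export
interval_duration <- function(intervals, fps = 4) {
  (intervals$end_frame - intervals$start_frame + 1) / fps
}

#' Read / write behaviour label tables
#'
#' Delimited text with header `bee_id,partner_id,behavior,start_frame,
#' end_frame`; empty `partner_id` fields are allowed and read as `NA`.
#'
#' @param path file path.
#' @return for `read_labels`, a [label_intervals()] table.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  req <- c("bee_id", "partner_id", "behavior", "start_frame", "end_frame")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stopf("label table '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  label_intervals(df$bee_id, df$behavior, df$start_frame, df$end_frame,
                  suppressWarnings(as.integer(df$partner_id)))
}

#' @rdname read_labels
#' @param labels a [label_intervals()] table.
#' @param sep field separator.
#' @export
write_labels <- function(labels, path, sep = ",") {
  df <- as.data.frame(labels)[, c("bee_id", "partner_id", "behavior",
                                  "start_frame", "end_frame")]
  df$partner_id[is.na(df$partner_id)] <- ""
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
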