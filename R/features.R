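#' Social per-frame features
#'
#' For every (bee, frame) detection, computes kinematic features (speed,
#' angular speed) and social features relative to the closest detected
#' nestmate in that frame: centre and head-to-head distances, the facing
#' angle of each bee toward the other, the difference between the two body
#' orientations, the closing speed and the neighbour count. The head point
#' of a bee is its centre displaced by half a body length along its
#' heading. A head-to-head encounter configuration corresponds to small
#' facing angles on both sides together with an orientation difference near
#' 180 degrees.
#'
#' Frames in which the focal bee has no detected nestmate carry `NA` in the
#' social channels; kinematic channels need the previous consecutive frame
#' and are `NA` at trajectory starts and after gaps. Missing values are
#' never fabricated.
#'
#' @param dataset a [tracking_dataset()].
#' @param body_length worker body length in mm; head offset is half this.
#' @param neighbor_radius radius in mm for the `n_neighbors` count.
#' @return data.frame of class `frame_features` with identifier columns
#'   `bee_id`, `frame`, `closest_id` and feature channels `speed` (mm/s),
#'   `angular_speed` (deg/s), `dist_center`, `dist_head` (mm),
#'   `facing_angle`, `partner_facing_angle`, `orientation_diff` (deg, in
#'   `[0, 180]`), `closing_speed` (mm/s, negative = approaching),
#'   `n_neighbors`. Attributes: `channels`, `fps`, `body_length`.
#' @export
compute_per_frame <- function(dataset, body_length = 13,
                              neighbor_radius = 30) {
  stopifnot(inherits(dataset, "tracking_dataset"), body_length > 0,
            neighbor_radius > 0)
  if (nrow(dataset) == 0) stopf("empty tracking dataset")
  fps <- attr(dataset, "fps")
  bees <- sort(unique(dataset$bee_id))
  fr <- attr(dataset, "frame_range")
  frames <- fr[1]:fr[2]
  nf <- length(frames); nb <- length(bees)

  # frame x bee matrices, NA where undetected
  ri <- match(dataset$frame, frames)
  ci <- match(dataset$bee_id, bees)
  idx <- cbind(ri, ci)
  Xm <- matrix(NA_real_, nf, nb); Ym <- Xm; Om <- Xm
  Xm[idx] <- dataset$x; Ym[idx] <- dataset$y; Om[idx] <- dataset$orientation

  half <- body_length / 2
  HX <- Xm + half * cos(Om * pi / 180)
  HY <- Ym + half * sin(Om * pi / 180)

  # kinematics from consecutive detected frames
  if (nf > 1) {
    speed <- rbind(NA_real_, sqrt(diff(Xm)^2 + diff(Ym)^2)) * fps
    dori <- rbind(NA_real_,
                  abs(angle_diff_signed(Om[-1, , drop = FALSE],
                                        Om[-nf, , drop = FALSE])))
  } else {
    speed <- matrix(NA_real_, 1, nb)
    dori <- speed
  }
  angular_speed <- dori * fps

  det <- !is.na(Xm)
  closest <- matrix(NA_integer_, nf, nb)
  dist_center <- matrix(NA_real_, nf, nb)
  dist_head <- matrix(NA_real_, nf, nb)
  facing <- matrix(NA_real_, nf, nb)
  pfacing <- matrix(NA_real_, nf, nb)
  odiff <- matrix(NA_real_, nf, nb)
  nneigh <- matrix(NA_real_, nf, nb)

  if (nb >= 2) {
    for (j in seq_len(nb)) {
      dx <- Xm - Xm[, j]; dy <- Ym - Ym[, j]
      D <- sqrt(dx^2 + dy^2)
      D[, j] <- Inf
      D[is.na(D)] <- Inf
      # closest other detected bee; ties broken by lower bee index
      k <- max.col(-D, ties.method = "first")
      dmin <- D[cbind(seq_len(nf), k)]
      ok <- det[, j] & is.finite(dmin)
      closest[ok, j] <- k[ok]
      dist_center[ok, j] <- dmin[ok]
      nneigh[det[, j], j] <- rowSums(D[det[, j], , drop = FALSE] <= neighbor_radius)
      rows <- which(ok)
      if (length(rows)) {
        kk <- k[rows]
        # bearing focal -> partner vs focal heading
        bear <- atan2(Ym[cbind(rows, kk)] - Ym[rows, j],
                      Xm[cbind(rows, kk)] - Xm[rows, j]) * 180 / pi
        facing[rows, j] <- angle_diff_abs(bear, Om[rows, j])
        bear_p <- atan2(Ym[rows, j] - Ym[cbind(rows, kk)],
                        Xm[rows, j] - Xm[cbind(rows, kk)]) * 180 / pi
        pfacing[rows, j] <- angle_diff_abs(bear_p, Om[cbind(rows, kk)])
        odiff[rows, j] <- angle_diff_abs(Om[cbind(rows, kk)], Om[rows, j])
        dist_head[rows, j] <- sqrt((HX[cbind(rows, kk)] - HX[rows, j])^2 +
                                     (HY[cbind(rows, kk)] - HY[rows, j])^2)
      }
    }
  } else {
    nneigh[det] <- 0
  }
  closing <- if (nf > 1) rbind(NA_real_, diff(dist_center)) * fps
             else matrix(NA_real_, 1, nb)

  out <- data.frame(
    bee_id = dataset$bee_id,
    frame = dataset$frame,
    closest_id = ifelse(is.na(closest[idx]), NA_integer_, bees[closest[idx]]),
    speed = speed[idx],
    angular_speed = angular_speed[idx],
    dist_center = dist_center[idx],
    dist_head = dist_head[idx],
    facing_angle = facing[idx],
    partner_facing_angle = pfacing[idx],
    orientation_diff = odiff[idx],
    closing_speed = closing[idx],
    n_neighbors = nneigh[idx])
  structure(out,
            channels = c("speed", "angular_speed", "dist_center", "dist_head",
                         "facing_angle", "partner_facing_angle",
                         "orientation_diff", "closing_speed", "n_neighbors"),
            fps = fps, body_length = body_length,
            class = c("frame_features", "data.frame"))
}

#' Windowed feature statistics
#'
#' For each per-frame channel and each window radius `w`, computes the
#' mean, min, max, standard deviation (population form, so `sd = 0` at
#' `w = 0`) and central difference (raw value minus windowed mean) over the
#' frames `t - w .. t + w`, truncated at trajectory ends. Missing frames
#' are excluded from the window statistics; a window with no observed
#' values yields `NA`. Radius 0 reproduces the raw channel with `sd` and
#' `diff` 0. Output columns are named `<channel>_w<r>_<stat>`; the total
#' feature-column count is `channels x radii x 5`.
#'
#' @param per_frame a [compute_per_frame()] result.
#' @param radii integer window radii in frames (default `c(1, 2, 4)`,
#'   i.e. 0.25-1 s at 4 fps).
#' @return data.frame of class `window_features` with `bee_id`, `frame`,
#'   `closest_id` and the windowed columns; attribute `channels` lists the
#'   feature column names.
#' @export
compute_window_features <- function(per_frame, radii = c(1, 2, 4)) {
  stopifnot(inherits(per_frame, "frame_features"), length(radii) >= 1,
            all(radii >= 0))
  channels <- attr(per_frame, "channels")
  bees <- sort(unique(per_frame$bee_id))
  frames <- min(per_frame$frame):max(per_frame$frame)
  nf <- length(frames); nb <- length(bees)
  idx <- cbind(match(per_frame$frame, frames), match(per_frame$bee_id, bees))

  shift_rows <- function(M, k) {
    # shift rows of M by k (k > 0: value from k frames later), NA-padded
    out <- matrix(NA_real_, nrow(M), ncol(M))
    if (k >= nrow(M) || -k >= nrow(M)) return(out)
    if (k >= 0) out[seq_len(nf - k), ] <- M[(k + 1):nf, , drop = FALSE]
    else out[(1 - k):nf, ] <- M[seq_len(nf + k), , drop = FALSE]
    out
  }

  out <- per_frame[, c("bee_id", "frame", "closest_id")]
  cols <- list()
  for (ch in channels) {
    M <- matrix(NA_real_, nf, nb)
    M[idx] <- per_frame[[ch]]
    for (r in radii) {
      S <- matrix(0, nf, nb); S2 <- S; C <- S
      Mn <- matrix(Inf, nf, nb); Mx <- matrix(-Inf, nf, nb)
      for (k in -r:r) {
        Mk <- shift_rows(M, k)
        obs <- !is.na(Mk)
        Mk0 <- ifelse(obs, Mk, 0)
        S <- S + Mk0; S2 <- S2 + Mk0^2; C <- C + obs
        Mn <- pmin(Mn, ifelse(obs, Mk, Inf))
        Mx <- pmax(Mx, ifelse(obs, Mk, -Inf))
      }
      mu <- ifelse(C > 0, S / C, NA_real_)
      sdv <- ifelse(C > 0, sqrt(pmax(S2 / C - (S / C)^2, 0)), NA_real_)
      Mn[!is.finite(Mn)] <- NA_real_
      Mx[!is.finite(Mx)] <- NA_real_
      dif <- M - mu
      pre <- sprintf("%s_w%d", ch, r)
      cols[[paste0(pre, "_mean")]] <- mu[idx]
      cols[[paste0(pre, "_min")]] <- Mn[idx]
      cols[[paste0(pre, "_max")]] <- Mx[idx]
      cols[[paste0(pre, "_sd")]] <- sdv[idx]
      cols[[paste0(pre, "_diff")]] <- dif[idx]
    }
  }
  out <- cbind(out, as.data.frame(cols))
  structure(out, channels = names(cols), fps = attr(per_frame, "fps"),
            class = c("window_features", "data.frame"))
}

#' Geometric head-to-head predicate
#'
#' A transparent baseline for the encounter configuration: TRUE for a
#' (bee, frame) iff the head-to-head distance to the closest bee is at most
#' `max_head_dist` and both facing angles are at most `max_facing`
#' (boundaries inclusive; strictly larger values fail). Frames with missing
#' social features are FALSE. The same predicate defines the simulator's
#' planted-encounter geometry.
#'
#' @param per_frame a [compute_per_frame()] result.
#' @param max_head_dist maximum head-to-head distance, mm.
#' @param max_facing maximum facing angle on both sides, degrees.
#' @return logical vector aligned with the rows of `per_frame`.
#' @export
head_to_head <- function(per_frame, max_head_dist = 4.5, max_facing = 25) {
  stopifnot(max_head_dist > 0, max_facing > 0)
  ok <- per_frame$dist_head <= max_head_dist &
    per_frame$facing_angle <= max_facing &
    per_frame$partner_facing_angle <= max_facing
  ok & !is.na(ok)
}

#' Write / read feature tables
#'
#' Feature matrices persist as delimited text with a channel-name header.
#'
#' @param features a `frame_features` or `window_features` data.frame.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE)
  invisible(path)
}
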