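#' Movement model parameters for the comb simulator
#'
#' Bees alternate between a resting state (small positional jitter, nearly
#' fixed heading) and a walking state (correlated random walk: heading
#' perturbed by a wrapped-normal turn each frame, step length drawn from a
#' normal truncated at zero). With `walk_step_mean` or `heading_sd` left
#' `NULL` they are calibrated analytically so that the resting/walking
#' mixture reproduces the target per-frame movement statistics observed in
#' tracked colonies: mean displacement 0.9 mm and mean absolute orientation
#' change 6 degrees per frame at 4 fps.
#'
#' @param p_rest stationary probability that a bee is resting.
#' @param walk_step_mean mean of the (untruncated) walking step-length
#'   normal, mm per frame; `NULL` = calibrate to `target_step`.
#' @param walk_step_sd SD of the walking step length, mm.
#' @param heading_sd SD of the per-frame walking heading change, degrees;
#'   `NULL` = calibrate to `target_dori`.
#' @param rest_jitter_sd per-axis SD of resting positional jitter, mm.
#' @param rest_heading_sd SD of the per-frame resting heading change, degrees.
#' @param switch_rate overall state-switch rate, events per second; the
#'   rest-to-walk rate is `switch_rate * (1 - p_rest)` and walk-to-rest
#'   `switch_rate * p_rest`, giving stationary resting occupancy `p_rest`.
#' @param target_step,target_dori calibration targets: mixture mean step
#'   (mm/frame) and mean |heading change| (deg/frame).
#' @return list of class `movement_params`.
#' @export
movement_params <- function(p_rest = 0.4, walk_step_mean = NULL,
                            walk_step_sd = 0.8, heading_sd = NULL,
                            rest_jitter_sd = 0.05, rest_heading_sd = 1.5,
                            switch_rate = 0.2,
                            target_step = 0.9, target_dori = 6) {
  stopifnot(p_rest >= 0, p_rest <= 1, walk_step_sd >= 0,
            rest_jitter_sd >= 0, rest_heading_sd >= 0, switch_rate >= 0)
  # Resting displacement is 2-D gaussian jitter => Rayleigh step length.
  rest_step_mean <- rest_jitter_sd * sqrt(pi / 2)
  if (is.null(walk_step_mean)) {
    if (p_rest >= 1) {
      walk_step_mean <- 0
    } else {
      target_walk <- (target_step - p_rest * rest_step_mean) / (1 - p_rest)
      if (target_walk <= 0) stopf("movement calibration infeasible: resting jitter alone exceeds target step")
      walk_step_mean <- stats::uniroot(
        function(m) truncnorm_mean(m, walk_step_sd) - target_walk,
        lower = -6 * walk_step_sd, upper = target_walk + 6 * walk_step_sd,
        tol = 1e-10)$root
    }
  }
  if (is.null(heading_sd)) {
    # E|N(0, s)| = s * sqrt(2/pi); wrapping negligible at these scales
    rest_dori <- rest_heading_sd * sqrt(2 / pi)
    if (p_rest >= 1) {
      heading_sd <- 0
    } else {
      heading_sd <- (target_dori - p_rest * rest_dori) /
        ((1 - p_rest) * sqrt(2 / pi))
      if (heading_sd < 0) stopf("movement calibration infeasible: resting heading jitter exceeds target")
    }
  }
  structure(list(p_rest = p_rest, walk_step_mean = walk_step_mean,
                 walk_step_sd = walk_step_sd, heading_sd = heading_sd,
                 rest_jitter_sd = rest_jitter_sd,
                 rest_heading_sd = rest_heading_sd,
                 switch_rate = switch_rate),
            class = "movement_params")
}

#' Encounter-bout duration model
#'
#' Per encounter class, bout durations follow a shifted log-normal
#' truncated to the observed support: `duration = min_s + X` with
#' `X ~ LogNormal(meanlog, sdlog)` upper-truncated at `max_s - min_s`.
#' `meanlog`/`sdlog` are fitted numerically so the truncated distribution
#' reproduces the published per-class median and 75th percentile exactly;
#' draws are quantised to the 0.25 s frame clock (4 fps) and clamped to the
#' support. Default supports and quantiles (seconds):
#' antennation [0.25, 9.25] median 1.8 q75 2.5; offering [0.25, 4.5]
#' median 1 q75 1.9; begging [0.75, 6.75] median 2 q75 3; trophallaxis
#' [5, 30.5] median 8 q75 12.9.
#'
#' @param quantiles data.frame with columns `behavior`, `min_s`, `max_s`,
#'   `median_s`, `q75_s`, one row per encounter class.
#' @return data.frame of class `duration_model` with fitted `meanlog`,
#'   `sdlog` per class.
#' @export
duration_model <- function(quantiles = NULL) {
  if (is.null(quantiles)) {
    quantiles <- data.frame(
      behavior = c("antennation", "offering", "begging", "trophallaxis"),
      min_s = c(0.25, 0.25, 0.75, 5),
      max_s = c(9.25, 4.5, 6.75, 30.5),
      median_s = c(1.8, 1, 2, 8),
      q75_s = c(2.5, 1.9, 3, 12.9))
  }
  stopifnot(all(c("behavior", "min_s", "max_s", "median_s", "q75_s")
                %in% names(quantiles)))
  with(quantiles, stopifnot(all(min_s <= median_s), all(median_s <= q75_s),
                            all(q75_s <= max_s), all(min_s >= 0)))
  fit1 <- function(min_s, max_s, med, q75) {
    u <- max_s - min_s
    m0 <- log(med - min_s)
    s0 <- (log(q75 - min_s) - m0) / stats::qnorm(0.75)
    obj <- function(par) {
      mu <- par[1]; sig <- exp(par[2])
      gu <- stats::pnorm((log(u) - mu) / sig)
      f <- function(x) stats::pnorm((log(x - min_s) - mu) / sig) / gu
      (f(med) - 0.5)^2 + (f(q75) - 0.75)^2
    }
    fit <- stats::optim(c(m0, log(s0)), obj, method = "Nelder-Mead",
                        control = list(reltol = 1e-14, maxit = 2000))
    c(meanlog = fit$par[1], sdlog = exp(fit$par[2]))
  }
  pars <- t(mapply(fit1, quantiles$min_s, quantiles$max_s,
                   quantiles$median_s, quantiles$q75_s))
  quantiles$meanlog <- pars[, "meanlog"]
  quantiles$sdlog <- pars[, "sdlog"]
  class(quantiles) <- c("duration_model", "data.frame")
  quantiles
}

#' Sample encounter-bout durations
#'
#' Draws durations for one encounter class from the fitted shifted,
#' truncated log-normal of a [duration_model()], quantised to 0.25 s.
#'
#' @param behavior one of [eb_classes()].
#' @param n number of draws.
#' @param model a [duration_model()].
#' @param seed optional integer; if given, draws use a private RNG stream.
#' @return numeric vector of durations in seconds, each within the class
#'   support.
#' @export
sample_bout_duration <- function(behavior, n = 1, model = duration_model(),
                                 seed = NULL) {
  if (!behavior %in% eb_classes())
    stopf("'%s' is not an encounter class; durations are modelled for %s",
          behavior, paste(eb_classes(), collapse = ", "))
  row <- model[model$behavior == behavior, ]
  if (nrow(row) != 1) stopf("duration model has no row for '%s'", behavior)
  with_seed(seed, {
    u <- row$max_s - row$min_s
    gu <- stats::pnorm((log(u) - row$meanlog) / row$sdlog)
    x <- exp(row$meanlog +
               row$sdlog * stats::qnorm(stats::runif(n) * gu))
    d <- row$min_s + x
    d <- round(d / 0.25) * 0.25
    pmin(pmax(d, row$min_s), row$max_s)
  })
}

#' Tag-detection dropout model
#'
#' Per-frame probability that a tag decoding fails, by movement state.
#' Defaults reproduce published detection rates: resting bees detected in
#' 98.2 % of frames, moving bees in 90.8 %.
#'
#' @param miss_prob_resting,miss_prob_moving miss probabilities in `[0, 1]`.
#' @return list of class `detection_model`.
#' @export
detection_model <- function(miss_prob_resting = 0.018,
                            miss_prob_moving = 0.092) {
  stopifnot(miss_prob_resting >= 0, miss_prob_resting <= 1,
            miss_prob_moving >= 0, miss_prob_moving <= 1)
  structure(list(miss_prob_resting = miss_prob_resting,
                 miss_prob_moving = miss_prob_moving),
            class = "detection_model")
}

#' Per-record movement state flags
#'
#' A bee counts as "moving" in a frame if its displacement from the
#' previous detected frame exceeds `threshold` mm (the first detection of a
#' trajectory inherits the flag of the following step). Used to apply
#' state-dependent detection dropout.
#'
#' @param dataset a [tracking_dataset()].
#' @param threshold displacement threshold, mm per frame.
#' @return character vector (`"moving"`/`"resting"`) aligned with the rows
#'   of `dataset`.
#' @export
movement_states <- function(dataset, threshold = 0.25) {
  n <- nrow(dataset)
  if (n == 0) return(character())
  same_bee <- c(FALSE, diff(dataset$bee_id) == 0)
  dx <- c(0, diff(dataset$x)); dy <- c(0, diff(dataset$y))
  step <- sqrt(dx^2 + dy^2)
  moving <- same_bee & step > threshold
  first <- which(!same_bee)
  nxt <- pmin(first + 1L, n)
  ok <- nxt <= n & c(diff(dataset$bee_id) == 0, FALSE)[first]
  moving[first[ok]] <- moving[nxt[ok]]
  ifelse(moving, "moving", "resting")
}

#' Apply state-dependent detection dropout
#'
#' Independently drops each record with the miss probability of its
#' movement state; surviving records are unchanged.
#'
#' @param dataset a dropout-free [tracking_dataset()].
#' @param states character vector (`"moving"`/`"resting"`) aligned with the
#'   rows of `dataset`; default computed by [movement_states()].
#' @param model a [detection_model()].
#' @param seed integer RNG seed.
#' @return a `tracking_dataset` containing the surviving records.
#' @export
degrade_detections <- function(dataset, states = movement_states(dataset),
                               model = detection_model(), seed = 1) {
  stopifnot(inherits(dataset, "tracking_dataset"),
            length(states) == nrow(dataset))
  miss_p <- ifelse(states == "moving", model$miss_prob_moving,
                   model$miss_prob_resting)
  keep <- with_seed(seed, stats::runif(nrow(dataset)) >= miss_p)
  tracking_dataset(as.data.frame(dataset)[keep, , drop = FALSE],
                   fps = attr(dataset, "fps"), arena = attr(dataset, "arena"),
                   validate = FALSE)
}

# Deterministic largest-deficit quota assignment of bout classes: keeps the
# empirical class mix within 1/n of the target mix for every prefix.
quota_next_class <- function(counts, mix) {
  deficit <- mix * (sum(counts) + 1) - counts
  names(counts)[which.max(deficit)]
}

#' Simulate a tagged-bee colony with planted encounter bouts
#'
#' Generates dropout-free trajectories of `n_bees` bees on one comb side.
#' Bees follow the two-state correlated random walk of
#' [movement_params()]; planted encounters steer two bees into a
#' head-to-head hold (head-to-head distance ~2.5 mm, facing angles within a
#' few degrees) for a duration drawn from the [duration_model()], then
#' release them. Bout classes are assigned by a deterministic quota rule so
#' the realised class mix tracks `class_mix` closely. Ground truth is the
#' planted schedule: one EB label interval per participating bee covering
#' the hold phase, plus NEB intervals (sitting/walking, from the scheduled
#' movement states) covering all non-encounter time. Outside planted
#' encounters no two bee centres come closer than 4 mm, and free bees keep
#' a wider berth (16 mm) around engaged pairs so that during a hold each
#' partner is the other's closest bee.
#'
#' @param n_bees number of bees (>= 1).
#' @param duration_s simulated time in seconds.
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @param movement a [movement_params()].
#' @param durations a [duration_model()].
#' @param encounter_rate planted bouts per bee-hour (each bee initiates
#'   encounters as a Poisson process at this rate while free).
#' @param class_mix named or ordered proportions over
#'   (antennation, offering, begging, trophallaxis); must sum to 1.
#' @param fps frames per second.
#' @param arena comb dimensions `c(width, height)` in mm; must allow at
#'   least 1 cm^2 per bee.
#' @param body_length worker body length in mm (head point offset =
#'   `body_length / 2`).
#' @return list with elements `tracking` (a [tracking_dataset()]),
#'   `labels` (a [label_intervals()] table: EB hold intervals with partner
#'   ids plus sitting/walking NEB intervals), `bouts` (data.frame of
#'   planted bouts: `bee_a`, `bee_b`, `behavior`, `start_frame`,
#'   `end_frame`, `duration_s`) and `states` (scheduled per-record
#'   `"moving"`/`"resting"` flags).
#' @export
simulate_colony <- function(n_bees, duration_s, seed = 1,
                            movement = movement_params(),
                            durations = duration_model(),
                            encounter_rate = 3.76,
                            class_mix = c(antennation = 0.57, offering = 0.26,
                                          begging = 0.09, trophallaxis = 0.08),
                            fps = 4, arena = c(370, 200), body_length = 13) {
  stopifnot(n_bees >= 1, duration_s > 0)
  if (abs(sum(class_mix) - 1) > 1e-8)
    stopf("class_mix must sum to 1 (got %g)", sum(class_mix))
  if (is.null(names(class_mix)))
    names(class_mix) <- c("antennation", "offering", "begging", "trophallaxis")
  if (prod(arena) / 100 < n_bees)
    stopf("arena of %g x %g mm is too small for %d bees at 1 bee/cm^2",
          arena[1], arena[2], n_bees)

  n_frames <- as.integer(round(duration_s * fps))
  hold_gap <- 2.5                      # head-to-head gap during hold, mm
  hold_dist <- body_length + hold_gap  # centre-to-centre distance
  approach_step <- 2.5                 # mm per approach frame
  max_approach <- 12L                  # frames (3 s at 4 fps)
  reach <- 25                          # partner search radius, mm
  floor_dist <- 4                      # centre floor between free bees, mm
  engaged_berth <- 16                  # free bees keep this far from engaged
  pair_spacing <- 35                   # min distance between bout sites, mm
  bystander_clear <- 25                # min free-bee distance from a new site
  margin <- 2

  with_seed(seed, {
    W <- arena[1]; H <- arena[2]
    # initial placement with pairwise floor
    X <- matrix(0, n_frames, n_bees); Y <- X; Hd <- X
    Smat <- matrix(1L, n_frames, n_bees)  # 1 rest, 2 walk, 3 approach, 4 hold
    px <- numeric(n_bees); py <- numeric(n_bees)
    for (b in seq_len(n_bees)) {
      repeat {
        cand <- c(stats::runif(1, margin + 3, W - margin - 3),
                  stats::runif(1, margin + 3, H - margin - 3))
        if (b == 1 || all(sqrt((px[seq_len(b - 1)] - cand[1])^2 +
                               (py[seq_len(b - 1)] - cand[2])^2) >= 6)) {
          px[b] <- cand[1]; py[b] <- cand[2]; break
        }
      }
    }
    hd <- stats::runif(n_bees, 0, 360)
    state <- ifelse(stats::runif(n_bees) < movement$p_rest, 1L, 2L)
    X[1, ] <- px; Y[1, ] <- py; Hd[1, ] <- hd; Smat[1, ] <- state

    p_r2w <- min(1, movement$switch_rate * (1 - movement$p_rest) / fps)
    p_w2r <- min(1, movement$switch_rate * movement$p_rest / fps)
    p_init <- if (n_bees >= 2) encounter_rate / 3600 / fps else 0

    counts <- stats::setNames(rep(0, length(class_mix)), names(class_mix))
    active <- list()    # each: a,b,behavior,phase,left,sx_a,sy_a,sx_b,sy_b,hold_left,hold_start,end
    engaged <- rep(FALSE, n_bees)
    want <- rep(FALSE, n_bees)   # drawn an initiation, waiting for a partner
    done_bouts <- list()

    for (f in 2:max(n_frames, 2)) {
      if (f > n_frames) break
      # --- bout phase transitions -------------------------------------
      if (length(active)) {
        keep <- logical(length(active))
        for (i in seq_along(active)) {
          bt <- active[[i]]
          if (bt$phase == "approach") {
            bt$left <- bt$left - 1L
            if (bt$left <= 0L) {
              bt$phase <- "hold"
              bt$hold_start <- f
            }
          } else if (bt$phase == "hold") {
            bt$hold_left <- bt$hold_left - 1L
            if (bt$hold_left <= 0L) {
              # release: record bout, free the bees, turn them apart
              bt$end <- f - 1L
              done_bouts[[length(done_bouts) + 1L]] <- bt
              engaged[c(bt$a, bt$b)] <- FALSE
              state[c(bt$a, bt$b)] <- 2L
              hd[c(bt$a, bt$b)] <- wrap360(hd[c(bt$a, bt$b)] + 180)
              keep[i] <- FALSE
              active[[i]] <- bt
              next
            }
          }
          active[[i]] <- bt
          keep[i] <- TRUE
        }
        active <- active[keep]
      }
      # --- new bout initiations (unserved initiations retry) ----------
      if (p_init > 0) {
        want <- want | (!engaged & stats::runif(n_bees) < p_init)
        for (a in which(want)) {
          if (engaged[a]) { want[a] <- FALSE; next }
          cand <- which(!engaged)
          cand <- cand[cand != a]
          if (!length(cand)) next
          d <- sqrt((px[cand] - px[a])^2 + (py[cand] - py[a])^2)
          if (min(d) > reach) next
          b <- cand[which.min(d)]
          mx <- min(max((px[a] + px[b]) / 2, 12), W - 12)
          my <- min(max((py[a] + py[b]) / 2, 12), H - 12)
          # keep bout sites clear of other engaged pairs and bystanders
          oth <- setdiff(seq_len(n_bees), c(a, b))
          if (length(oth)) {
            do <- sqrt((px[oth] - mx)^2 + (py[oth] - my)^2)
            if (any(do < ifelse(engaged[oth], pair_spacing, bystander_clear)))
              next
          }
          ux <- px[b] - px[a]; uy <- py[b] - py[a]
          nl <- sqrt(ux^2 + uy^2)
          if (nl < 1e-9) { ux <- 1; uy <- 0 } else { ux <- ux / nl; uy <- uy / nl }
          beh <- quota_next_class(counts, class_mix)
          counts[beh] <- counts[beh] + 1
          dur <- sample_bout_duration(beh, 1, durations)
          sxa <- mx - ux * hold_dist / 2; sya <- my - uy * hold_dist / 2
          sxb <- mx + ux * hold_dist / 2; syb <- my + uy * hold_dist / 2
          da <- sqrt((px[a] - sxa)^2 + (py[a] - sya)^2)
          db <- sqrt((px[b] - sxb)^2 + (py[b] - syb)^2)
          nappr <- min(max_approach,
                       max(2L, as.integer(ceiling(max(da, db) / approach_step)) + 1L))
          active[[length(active) + 1L]] <-
            list(a = a, b = b, behavior = beh, phase = "approach",
                 left = nappr, sx_a = sxa, sy_a = sya, sx_b = sxb,
                 sy_b = syb, hold_left = as.integer(round(dur * fps)),
                 hold_start = NA_integer_, end = NA_integer_,
                 duration_s = dur)
          engaged[c(a, b)] <- TRUE
          want[c(a, b)] <- FALSE
        }
      }
      # --- free-bee state switching -----------------------------------
      free <- !engaged
      sw <- stats::runif(n_bees)
      to_walk <- free & state == 1L & sw < p_r2w
      to_rest <- free & state == 2L & sw < p_w2r
      state[to_walk] <- 2L; state[to_rest] <- 1L

      # --- propose moves ----------------------------------------------
      nx <- px; ny <- py; nh <- hd
      rest_i <- which(free & state == 1L)
      if (length(rest_i)) {
        nx[rest_i] <- px[rest_i] + stats::rnorm(length(rest_i), 0, movement$rest_jitter_sd)
        ny[rest_i] <- py[rest_i] + stats::rnorm(length(rest_i), 0, movement$rest_jitter_sd)
        nh[rest_i] <- wrap360(hd[rest_i] + stats::rnorm(length(rest_i), 0, movement$rest_heading_sd))
      }
      walk_i <- which(free & state == 2L)
      if (length(walk_i)) {
        # soft wall avoidance: inside a 12 mm buffer the mean turn is biased
        # toward the arena interior, which prevents bees accumulating along
        # the walls without the heading jumps a hard reflection would cause
        buf <- 12
        vx <- pmax(0, buf - px[walk_i]) / buf -
          pmax(0, px[walk_i] - (W - buf)) / buf
        vy <- pmax(0, buf - py[walk_i]) / buf -
          pmax(0, py[walk_i] - (H - buf)) / buf
        bias <- numeric(length(walk_i))
        nearw <- which(vx != 0 | vy != 0)
        if (length(nearw)) {
          outward <- atan2(-vy[nearw], -vx[nearw]) * 180 / pi
          delta <- angle_diff_signed(hd[walk_i][nearw], outward)
          strength <- pmin(1, sqrt(vx[nearw]^2 + vy[nearw]^2))
          # rotate only headings pointing outward, toward the nearer tangent
          ptg <- abs(delta) < 90
          if (any(ptg)) {
            turn <- (sign(delta[ptg]) + (delta[ptg] == 0)) * 95 - delta[ptg]
            bias[nearw[ptg]] <- pmax(pmin(turn * 0.3 * strength[ptg], 12), -12)
          }
        }
        nh[walk_i] <- wrap360(hd[walk_i] + bias +
                                stats::rnorm(length(walk_i), 0, movement$heading_sd))
        stp <- rtruncnorm0(length(walk_i), movement$walk_step_mean, movement$walk_step_sd)
        nx[walk_i] <- px[walk_i] + stp * cos(nh[walk_i] * pi / 180)
        ny[walk_i] <- py[walk_i] + stp * sin(nh[walk_i] * pi / 180)
      }
      for (bt in active) {
        for (side in c("a", "b")) {
          id <- bt[[side]]
          sx <- bt[[paste0("sx_", side)]]; sy <- bt[[paste0("sy_", side)]]
          ox <- bt[[paste0("sx_", if (side == "a") "b" else "a")]]
          oy <- bt[[paste0("sy_", if (side == "a") "b" else "a")]]
          face <- wrap360(atan2(oy - sy, ox - sx) * 180 / pi)
          if (bt$phase == "approach") {
            dx <- sx - px[id]; dy <- sy - py[id]
            d <- sqrt(dx^2 + dy^2)
            if (bt$left <= 1L || d < 1e-6) {   # final frame: snap into slot
              nx[id] <- sx; ny[id] <- sy
              nh[id] <- face
            } else {
              stp <- min(d, approach_step)
              nx[id] <- px[id] + stp * dx / d
              ny[id] <- py[id] + stp * dy / d
              tgt <- wrap360(atan2(dy, dx) * 180 / pi)
              turn <- angle_diff_signed(tgt, hd[id])
              nh[id] <- wrap360(hd[id] + sign(turn) * min(abs(turn), 45))
            }
            state[id] <- 3L
          } else {  # hold: small jitter around the slot, facing partner
            nx[id] <- sx + stats::rnorm(1, 0, 0.1)
            ny[id] <- sy + stats::rnorm(1, 0, 0.1)
            nh[id] <- wrap360(face + stats::rnorm(1, 0, 2))
            state[id] <- 4L
          }
        }
      }
      # --- walls: reflect positions into the margin box ---------------
      nx <- ifelse(nx < margin, 2 * margin - nx,
                   ifelse(nx > W - margin, 2 * (W - margin) - nx, nx))
      ny <- ifelse(ny < margin, 2 * margin - ny,
                   ifelse(ny > H - margin, 2 * (H - margin) - ny, ny))
      nx <- pmin(pmax(nx, margin), W - margin)
      ny <- pmin(pmax(ny, margin), H - margin)
      # --- collision resolution: push free bees apart (engaged bees
      # hold their choreography; free bees yield) -----------------------
      for (it in 1:4) {
        dxm <- outer(nx, nx, "-"); dym <- outer(ny, ny, "-")
        D <- sqrt(dxm^2 + dym^2)
        lim <- matrix(floor_dist, n_bees, n_bees)
        if (any(engaged)) {
          lim[, engaged] <- engaged_berth
          lim[engaged, ] <- engaged_berth
          lim[engaged, engaged] <- 0   # choreographed pairs manage themselves
        }
        # berth (soft) violations are pushed once per frame; later sweeps
        # only clean up hard floor violations the pushes may have created
        if (it > 1) lim[lim == engaged_berth] <- floor_dist
        D[upper.tri(D, diag = TRUE)] <- Inf
        viol <- which(D < lim, arr.ind = TRUE)
        if (!nrow(viol)) break
        for (v in seq_len(nrow(viol))) {
          i <- viol[v, 1]; j <- viol[v, 2]
          if (engaged[i] && engaged[j]) next
          d <- sqrt((nx[i] - nx[j])^2 + (ny[i] - ny[j])^2)
          tgt <- lim[i, j] + 0.05
          if (d < 1e-9) { ux <- 1; uy <- 0; d <- 1e-9 }
          else { ux <- (nx[i] - nx[j]) / d; uy <- (ny[i] - ny[j]) / d }
          # limit per-frame push so berths engage gradually
          push <- min(tgt - d, 1.5)
          if (!engaged[i] && !engaged[j]) {
            nx[i] <- nx[i] + ux * push / 2; ny[i] <- ny[i] + uy * push / 2
            nx[j] <- nx[j] - ux * push / 2; ny[j] <- ny[j] - uy * push / 2
          } else if (!engaged[i]) {
            nx[i] <- nx[i] + ux * push; ny[i] <- ny[i] + uy * push
          } else {
            nx[j] <- nx[j] - ux * push; ny[j] <- ny[j] - uy * push
          }
        }
        nx <- pmin(pmax(nx, margin), W - margin)
        ny <- pmin(pmax(ny, margin), H - margin)
      }
      # hard-floor fallback: any free bee still violating (e.g. pinned by a
      # wall clamp) reverts to its previous, valid position
      for (it in 1:3) {
        dxm <- outer(nx, nx, "-"); dym <- outer(ny, ny, "-")
        D <- sqrt(dxm^2 + dym^2)
        diag(D) <- Inf
        lim <- matrix(floor_dist, n_bees, n_bees)
        if (any(engaged)) lim[engaged, engaged] <- 0
        bad <- which(!engaged & rowSums(D < lim) > 0)
        if (!length(bad)) break
        nx[bad] <- px[bad]; ny[bad] <- py[bad]
      }
      px <- nx; py <- ny; hd <- nh
      X[f, ] <- px; Y[f, ] <- py; Hd[f, ] <- hd; Smat[f, ] <- state
    }

    # bouts still unfinished when the recording ends are discarded: their
    # realised duration would not match the planted one, so they are not
    # ground truth (their frames stay unlabelled, like ambiguous video)

    # --- assemble outputs (frames are 0-based) ------------------------
    records <- data.frame(
      bee_id = rep(seq_len(n_bees), each = n_frames),
      frame = rep(0:(n_frames - 1L), n_bees),
      time = round(rep(0:(n_frames - 1L), n_bees) / fps, 2),
      x = round(as.vector(X), 3),
      y = round(as.vector(Y), 3),
      orientation = round(wrap360(as.vector(Hd)), 3))
    records$orientation[records$orientation >= 360] <- 0
    tracking <- tracking_dataset(records, fps = fps, arena = arena)

    bouts <- if (length(done_bouts)) {
      data.frame(
        bee_a = vapply(done_bouts, `[[`, 0L, "a"),
        bee_b = vapply(done_bouts, `[[`, 0L, "b"),
        behavior = vapply(done_bouts, `[[`, "", "behavior"),
        start_frame = vapply(done_bouts, function(b) b$hold_start - 1L, 0L),
        end_frame = vapply(done_bouts, function(b) b$end - 1L, 0L),
        duration_s = vapply(done_bouts, `[[`, 0, "duration_s"))
    } else {
      data.frame(bee_a = integer(), bee_b = integer(), behavior = character(),
                 start_frame = integer(), end_frame = integer(),
                 duration_s = numeric())
    }

    # EB labels: one interval per participant per bout
    if (nrow(bouts)) {
      eb <- label_intervals(
        bee_id = c(bouts$bee_a, bouts$bee_b),
        behavior = rep(bouts$behavior, 2),
        start_frame = rep(bouts$start_frame, 2),
        end_frame = rep(bouts$end_frame, 2),
        partner_id = c(bouts$bee_b, bouts$bee_a))
    } else eb <- NULL

    # NEB labels: runs of scheduled sitting/walking per bee
    neb_list <- vector("list", n_bees)
    for (b in seq_len(n_bees)) {
      s <- Smat[, b]
      lab <- ifelse(s == 1L, "sitting",
                    ifelse(s == 2L | s == 3L, "walking", NA_character_))
      r <- rle(lab)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      ok <- !is.na(r$values)
      if (any(ok))
        neb_list[[b]] <- data.frame(bee_id = b, behavior = r$values[ok],
                                    start_frame = starts[ok] - 1L,
                                    end_frame = ends[ok] - 1L)
    }
    neb_df <- do.call(rbind, neb_list)
    neb <- if (!is.null(neb_df) && nrow(neb_df))
      label_intervals(neb_df$bee_id, neb_df$behavior, neb_df$start_frame,
                      neb_df$end_frame) else NULL
    labels <- rbind(eb, neb)
    if (is.null(labels))
      labels <- label_intervals(integer(), character(), integer(), integer())
    class(labels) <- c("label_intervals", "data.frame")
    rownames(labels) <- NULL

    # scheduled movement state per record ("hold"/"rest" => resting-like)
    sched <- ifelse(as.vector(Smat) %in% c(2L, 3L), "moving", "resting")

    list(tracking = tracking, labels = labels, bouts = bouts, states = sched)
  })
}
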