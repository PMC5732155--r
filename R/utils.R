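# Internal helpers: circular arithmetic in degrees, scoped RNG, misc.

# Wrap angles into [0, 360).
wrap360 <- function(a) {
  a <- a %% 360
  a[which(a < 0)] <- a[which(a < 0)] + 360
  # %% can return 360 for tiny negative inputs due to fp; clamp
  a[which(a >= 360)] <- 0
  a
}

# Signed shortest-arc difference a - b, in (-180, 180]; NA-safe.
angle_diff_signed <- function(a, b) {
  d <- (a - b) %% 360
  d[which(d > 180)] <- d[which(d > 180)] - 360
  d
}

# Absolute shortest-arc difference, in [0, 180].
angle_diff_abs <- function(a, b) abs(angle_diff_signed(a, b))

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb
# user-level random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically derive a substream seed from a master seed and a stage
# label; keeps results below 2^31 and decorrelates stages.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 12345) %% 2147483629)
}

# Mean of a normal(mean, sd) truncated to [0, Inf).
truncnorm_mean <- function(mean, sd) {
  if (sd <= 0) return(max(mean, 0))
  a <- -mean / sd
  mean + sd * exp(stats::dnorm(a, log = TRUE) -
                    stats::pnorm(a, lower.tail = FALSE, log.p = TRUE))
}

# Draw from normal(mean, sd) truncated to [0, Inf) by inverse CDF.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(max(mean, 0), n))
  p0 <- stats::pnorm(0, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
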