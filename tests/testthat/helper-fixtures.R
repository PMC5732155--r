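# Shared fixtures and independent oracles, built in code at test time.

# Hand-built grid-valued tracking records that survive file round-trips.
toy_records <- function() {
  data.frame(
    bee_id = c(1L, 1L, 1L, 2L, 2L),
    frame = c(0L, 1L, 2L, 0L, 2L),
    time = c(0, 0.25, 0.5, 0, 0.5),
    x = c(10, 10.9, 11.8, 50, 52),
    y = c(20, 20, 20, 60, 60.5),
    orientation = c(0, 5.25, 10.5, 180, 175.125))
}

# Memoised medium-sized colony simulation shared by several test files.
.sim_cache <- new.env(parent = emptyenv())
sim_medium <- function() {
  if (is.null(.sim_cache$sim))
    .sim_cache$sim <- simulate_colony(20, 900, seed = 4242)
  .sim_cache$sim
}

# Expand label intervals into per-(bee, frame) keys.
interval_keys <- function(labels, rows) {
  unlist(lapply(rows, function(i)
    paste(labels$bee_id[i], labels$start_frame[i]:labels$end_frame[i])))
}

# --- independent brute-force rank oracles ------------------------------

# Midranks computed by explicit counting, no call to rank().
brute_ranks <- function(values) {
  vapply(values, function(v)
    sum(values < v) + (sum(values == v) + 1) / 2, 0)
}

# Kruskal-Wallis H with tie correction, from the textbook rank-sum formula.
brute_kruskal_H <- function(values, groups) {
  r <- brute_ranks(values)
  N <- length(values)
  H <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    H <- H + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  H <- H * 12 / (N * (N + 1))
  tie_sizes <- as.vector(table(values))
  corr <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  if (corr == 0) 0 else H / corr
}

# Dunn's Q per pair from first principles.
brute_dunn_Q <- function(values, groups, gi, gj) {
  r <- brute_ranks(values)
  N <- length(values)
  tie_sizes <- as.vector(table(values))
  tcorr <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  ri <- mean(r[groups == gi]); rj <- mean(r[groups == gj])
  ni <- sum(groups == gi); nj <- sum(groups == gj)
  se <- sqrt((N * (N + 1) / 12 - tcorr) * (1 / ni + 1 / nj))
  if (se == 0) 0 else abs(ri - rj) / se
}

# Minimal feature table (with channels attribute) for classifier tests.
fake_features <- function(values, bee_id = 1L, channels = "f1") {
  df <- data.frame(bee_id = bee_id, frame = seq_along(values) - 1L)
  df[[channels[1]]] <- values
  attr(df, "channels") <- channels
  df
}
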