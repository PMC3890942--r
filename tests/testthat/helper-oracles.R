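# Independent brute-force oracles, deliberately written without run-length
# tricks so they share no code path with the implementation.

# Step-by-step contact counter: walks the series, opens a contact at a 0->1
# transition, accumulates the set of overlapping types, closes at 1->0.
oracle_contact_counts <- function(stim, overlaps) {
  counts <- c(avatar = 0L, shadow = 0L, static = 0L)
  open <- FALSE
  types <- character(0)
  n <- length(stim)
  for (i in seq_len(n)) {
    if (stim[i]) {
      if (!open) {
        open <- TRUE
        types <- character(0)
      }
      for (ty in c("avatar", "shadow", "static")) {
        if (overlaps[[ty]][i]) types <- union(types, ty)
      }
      if (i == n || !stim[i + 1]) { # run closes here
        counts[types] <- counts[types] + 1L
        open <- FALSE
      }
    }
  }
  counts
}

# Brute-force movement binarization: raw threshold, then for every raw-0
# step scan outwards to measure the full run it sits in.
oracle_binarize <- function(positions, cfg) {
  L <- cfg$space_length
  n <- length(positions) - 1
  dx <- numeric(n)
  for (i in seq_len(n)) {
    d <- (positions[i + 1] - positions[i]) %% L
    if (d > L / 2) d <- d - L
    dx[i] <- abs(d)
  }
  raw <- as.integer(dx > cfg$move_threshold)
  out <- raw
  for (i in seq_len(n)) {
    if (raw[i] == 0L) {
      lo <- i
      while (lo > 1 && raw[lo - 1] == 0L) lo <- lo - 1
      hi <- i
      while (hi < n && raw[hi + 1] == 0L) hi <- hi + 1
      out[i] <- if (hi - lo + 1 >= cfg$min_pause_steps) 0L else 1L
    }
  }
  out
}

# Pooled-variance one-tailed t-test from the textbook formulas.
oracle_pooled_t <- function(x, y, larger = c("x", "y")) {
  larger <- match.arg(larger)
  n1 <- length(x)
  n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  p <- if (larger == "x") pt(t, df, lower.tail = FALSE) else pt(t, df)
  list(t = t, df = df, p = p)
}

# Random overlap channels whose OR defines the stimulation series.
random_overlap_instance <- function(n, p = 0.35) {
  ov <- tibble::tibble(
    avatar = runif(n) < p,
    shadow = runif(n) < p,
    static = runif(n) < p
  )
  list(stim = ov$avatar | ov$shadow | ov$static, overlaps = ov)
}

# A wrapped random-walk position series with occasional pauses.
random_walk_positions <- function(n, cfg) {
  steps <- sample(
    c(0, 0.2, 0.7, 1.5), n - 1,
    replace = TRUE, prob = c(0.4, 0.2, 0.25, 0.15)
  )
  # inject a few long pauses
  if (n > 120) {
    at <- sample(seq_len(n - 61), 2)
    for (a in at) steps[a:(a + 59)] <- 0
  }
  wrap_position(cumsum(c(runif(1, 0, cfg$space_length), steps)),
    cfg$space_length
  )
}

# Small two-player recording built directly from scripted positions, for
# attribution and turn-taking tests with hand-chosen geometry.
make_recording <- function(pos1, pos2, static_pos, cfg = env_config(),
                           clicks = NULL) {
  n <- length(pos1)
  rec <- structure(
    list(
      cfg = cfg,
      steps = tibble::tibble(
        step = 0:(n - 1), time_ms = (0:(n - 1)) * cfg$sample_period,
        pos1 = wrap_position(pos1, cfg$space_length),
        pos2 = wrap_position(pos2, cfg$space_length),
        stim1 = FALSE, stim2 = FALSE
      ),
      static_pos = static_pos,
      clicks = clicks %||%
        tibble::tibble(player = integer(), step = integer(), time_ms = numeric()),
      meta = list(team = 1L, trial = 1L, shadow_sign = 1)
    ),
    class = "trial_recording"
  )
  for (p in 1:2) {
    ov <- overlap_channels(rec, p)
    s <- ov$avatar | ov$shadow | ov$static
    if (p == 1) rec$steps$stim1 <- s else rec$steps$stim2 <- s
  }
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
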