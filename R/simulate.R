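#' Simulate one perceptual-crossing trial
#'
#' Runs two [agent controllers][make_scanner_agent] for one trial in the
#' wrap-around 1D environment. Each player's avatar carries a binary contact
#' sensor; a shadow object is rigidly attached to each avatar at
#' `cfg$shadow_offset` units (same sign for both players, recorded in the
#' trial metadata), and each player additionally has one private static
#' object that only its owner can feel. A player is stimulated at a step when
#' its avatar overlaps the other's avatar, the other's shadow, or its own
#' static object. Touching the other's shadow stimulates only the toucher;
#' mutual avatar contact stimulates both.
#'
#' At most one click per player is retained; any later clicks are discarded.
#'
#' @param controllers List of two `agent_controller` objects.
#' @param cfg An [env_config()].
#' @param seed Integer seed for start/static placement when these are not
#'   supplied.
#' @param starts Optional numeric(2): starting avatar positions.
#' @param static_pos Optional numeric(2): the two static-object positions.
#'   When drawn randomly they are kept at least `static_clearance` units from
#'   both starting positions so that no one spawns in contact.
#' @param static_clearance Minimum wrapped distance from either start to a
#'   randomly placed static object, in units.
#' @param meta Named list of metadata (team, trial, scenario labels, ...).
#' @return A `trial_recording`: a list with elements `cfg`, `steps` (a tibble
#'   with columns `step`, `time_ms`, `pos1`, `pos2`, `stim1`, `stim2`),
#'   `static_pos`, `clicks` (tibble `player`, `step`, `time_ms`), and `meta`.
#'   Steps are 0-based; `time_ms = step * cfg$sample_period`.
#' @examples
#' rec <- simulate_trial(
#'   list(make_stationary_agent(), make_stationary_agent()),
#'   env_config(),
#'   seed = 1, starts = c(0, 300), static_pos = c(100, 450)
#' )
#' sum(rec$steps$stim1)
#' @export
simulate_trial <- function(controllers, cfg = env_config(), seed = NULL,
                           starts = NULL, static_pos = NULL,
                           static_clearance = 2 * cfg$body_length,
                           meta = list()) {
  stopifnot(length(controllers) == 2)
  if (!all(vapply(controllers, inherits, logical(1), "agent_controller"))) {
    stop("`controllers` must be a list of two agent_controller objects.",
      call. = FALSE
    )
  }
  validate_env_config(cfg)
  L <- cfg$space_length
  n <- n_steps(cfg)
  if (!is.null(seed)) {
    draws <- with_local_seed(seed, stats::runif(20, 0, L))
  } else {
    draws <- stats::runif(20, 0, L)
  }
  if (is.null(starts)) starts <- draws[1:2]
  starts <- wrap_position(as.numeric(starts), L)
  if (is.null(static_pos)) {
    static_pos <- c(NA_real_, NA_real_)
    k <- 3L
    for (p in 1:2) {
      repeat {
        cand <- if (k <= length(draws)) draws[k] else stats::runif(1, 0, L)
        k <- k + 1L
        d <- abs(signed_displacement(starts, cand, L))
        if (all(d >= static_clearance)) {
          static_pos[p] <- cand
          break
        }
      }
    }
  }
  static_pos <- wrap_position(as.numeric(static_pos), L)

  pos1 <- numeric(n)
  pos2 <- numeric(n)
  stim1 <- logical(n)
  stim2 <- logical(n)
  pos1[1] <- starts[1]
  pos2[1] <- starts[2]
  click_step <- c(NA_integer_, NA_integer_)
  st1 <- controllers[[1]]$init()
  st2 <- controllers[[2]]$init()
  mv1 <- controllers[[1]]$move
  mv2 <- controllers[[2]]$move
  body <- cfg$body_length
  off <- cfg$shadow_offset
  half <- L / 2

  # Scalar twin of objects_overlap(); argument order matters at the ulp
  # level, so the mutual avatar overlap is evaluated once in the canonical
  # (player 1, player 2) order — exactly as overlap_channels() recomputes it.
  ov <- function(a, b) {
    d <- (b - a) %% L
    if (d > half) d <- d - L
    abs(d) < body
  }

  for (i in seq_len(n)) {
    p1 <- pos1[i]
    p2 <- pos2[i]
    d_av <- ov(p1, p2) # other's avatar (mutual, canonical order)
    s1 <- d_av ||
      ov(p1, (p2 + off) %% L) || # other's shadow
      ov(p1, static_pos[1]) # own static
    s2 <- d_av ||
      ov(p2, (p1 + off) %% L) ||
      ov(p2, static_pos[2])
    stim1[i] <- s1
    stim2[i] <- s2
    t0 <- i - 1L
    r1 <- mv1(st1, t0, p1, s1)
    r2 <- mv2(st2, t0, p2, s2)
    st1 <- r1$state
    st2 <- r2$state
    if (r1$click && is.na(click_step[1])) click_step[1] <- t0
    if (r2$click && is.na(click_step[2])) click_step[2] <- t0
    if (i < n) {
      if (!is.finite(r1$vel)) {
        stop(sprintf("Controller for player 1 emitted a non-finite velocity at step %d.", t0),
          call. = FALSE
        )
      }
      if (!is.finite(r2$vel)) {
        stop(sprintf("Controller for player 2 emitted a non-finite velocity at step %d.", t0),
          call. = FALSE
        )
      }
      pos1[i + 1L] <- (p1 + r1$vel) %% L
      pos2[i + 1L] <- (p2 + r2$vel) %% L
    }
  }

  clicks <- tibble::tibble(
    player = c(1L, 2L)[!is.na(click_step)],
    step = click_step[!is.na(click_step)]
  )
  clicks$time_ms <- clicks$step * cfg$sample_period

  structure(
    list(
      cfg = cfg,
      steps = tibble::tibble(
        step = 0:(n - 1L),
        time_ms = (0:(n - 1L)) * cfg$sample_period,
        pos1 = pos1, pos2 = pos2,
        stim1 = stim1, stim2 = stim2
      ),
      static_pos = static_pos,
      clicks = clicks,
      meta = utils::modifyList(
        list(seed = seed, shadow_sign = 1),
        meta
      )
    ),
    class = "trial_recording"
  )
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording: %d steps (%g s at %g Hz), %d click(s)>\n",
    nrow(x$steps), x$cfg$trial_duration, 1000 / x$cfg$sample_period,
    nrow(x$clicks)
  ))
  invisible(x)
}

#' Derived per-step geometry of a trial recording
#'
#' `shadow_positions()` returns the wrapped positions of a player's shadow
#' (avatar position plus the rigid offset). `overlap_channels()` returns, for
#' one player, the three per-step overlap indicators underlying that player's
#' stimulation: contact with the other's avatar, with the other's shadow, and
#' with the player's own static object. These are recomputed from positions,
#' so they are consistent with the recording by construction.
#'
#' @param rec A `trial_recording`.
#' @param player 1 or 2.
#' @return `shadow_positions()`: numeric vector. `overlap_channels()`: a
#'   tibble with logical columns `avatar`, `shadow`, `static`.
#' @export
shadow_positions <- function(rec, player) {
  pos <- if (player == 1) rec$steps$pos1 else rec$steps$pos2
  wrap_position(pos + rec$meta$shadow_sign * rec$cfg$shadow_offset,
    L = rec$cfg$space_length
  )
}

#' @rdname shadow_positions
#' @export
overlap_channels <- function(rec, player) {
  stopifnot(player %in% c(1, 2))
  own <- if (player == 1) rec$steps$pos1 else rec$steps$pos2
  tibble::tibble(
    # mutual contact: evaluated once in canonical (player 1, player 2) order
    # so the channel is exactly symmetric between the two players
    avatar = objects_overlap(rec$steps$pos1, rec$steps$pos2, rec$cfg),
    shadow = objects_overlap(own, shadow_positions(rec, 3 - player), rec$cfg),
    static = objects_overlap(own, rec$static_pos[player], rec$cfg)
  )
}

player_stim <- function(rec, player) {
  if (player == 1) rec$steps$stim1 else rec$steps$stim2
}

player_positions <- function(rec, player) {
  if (player == 1) rec$steps$pos1 else rec$steps$pos2
}
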