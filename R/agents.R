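# Scripted agent controllers standing in for human players.
#
# A controller observes only its own state: its avatar position and its own
# binary tactile stimulation. Each controller is a list with
#   init(): returns its initial private state, and
#   move(state, t, pos, stim): returns list(vel, click, state)
# where t is the 0-based step index, pos the wrapped avatar position, stim
# the player's stimulation at step t, vel the velocity command (units/step)
# applied from t to t+1, and click TRUE when the player clicks at step t.

new_agent_controller <- function(init, move, label, params = list()) {
  structure(
    list(init = init, move = move, label = label, params = params),
    class = "agent_controller"
  )
}

#' @export
print.agent_controller <- function(x, ...) {
  cat("<agent_controller:", x$label, ">\n")
  invisible(x)
}

# Draw from a private RNG stream without disturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(seed)
  force(expr)
}

#' Scripted sweeping "scanner" agent
#'
#' Emulates a player searching the circle: the avatar sweeps back and forth
#' over an arc of `span` units at constant `speed`, reversing at the arc ends.
#' `span = 0` yields a stationary agent; a span equal to the space length
#' yields a full-circle patrol. The click policy arms itself at a seeded time
#' inside `click_window` and clicks at the first stimulated step thereafter,
#' so clicks land on whatever object the sweep happens to be touching.
#'
#' @param speed Sweep speed in units/step; must be positive.
#' @param span Arc length covered by the sweep, in units.
#' @param seed Integer seed for the agent's private randomness (initial
#'   direction, phase, and click arming time). `NULL` disables clicking
#'   randomness (arming at the start of `click_window`).
#' @param click_window Two-element numeric, seconds: the arming time is drawn
#'   uniformly in this interval. Use `c(Inf, Inf)` for a non-clicking agent.
#' @param sample_period Sample period in ms (to convert `click_window`).
#' @return An `agent_controller`.
#' @examples
#' a <- make_scanner_agent(speed = 1, span = 600, seed = 1)
#' @export
make_scanner_agent <- function(speed = 0.6, span = 200, seed = NULL,
                               click_window = c(15, 55),
                               sample_period = 10) {
  if (!is.numeric(speed) || speed <= 0) {
    stop("`speed` must be positive.", call. = FALSE)
  }
  if (span < 0) stop("`span` must be non-negative.", call. = FALSE)
  draws <- if (is.null(seed)) {
    list(dir = 1, phase = 0, arm_s = click_window[1])
  } else {
    with_local_seed(seed, list(
      dir = sample(c(-1, 1), 1),
      phase = stats::runif(1, 0, max(span, 1e-9)),
      arm_s = stats::runif(1, click_window[1], click_window[2])
    ))
  }
  arm_step <- draws$arm_s * 1000 / sample_period
  init <- function() {
    list(offset = min(draws$phase, span), dir = draws$dir, clicked = FALSE)
  }
  move <- function(state, t, pos, stim) {
    click <- FALSE
    if (!state$clicked && is.finite(arm_step) && t >= arm_step && stim) {
      click <- TRUE
      state$clicked <- TRUE
    }
    if (span == 0) {
      return(list(vel = 0, click = click, state = state))
    }
    nxt <- state$offset + state$dir * speed
    if (nxt > span || nxt < 0) state$dir <- -state$dir
    vel <- state$dir * speed
    state$offset <- state$offset + vel
    list(vel = vel, click = click, state = state)
  }
  new_agent_controller(
    init, move,
    label = "scanner",
    params = list(speed = speed, span = span, seed = seed)
  )
}

#' Stationary agent
#'
#' A degenerate scanner with zero span and no click policy; useful as an
#' unresponsive partner in control scenarios.
#' @return An `agent_controller`.
#' @export
make_stationary_agent <- function() {
  ctrl <- make_scanner_agent(
    speed = 1, span = 0, seed = NULL,
    click_window = c(Inf, Inf)
  )
  ctrl$label <- "stationary"
  ctrl
}

#' Scripted turn-taking agent
#'
#' Emulates the coordinated behaviour observed in successful pairs: once the
#' agent has confirmed sustained contact (its own stimulation held for
#' `confirm_steps` consecutive steps, monitored from `start_delay_steps`
#' onwards), it enters an alternation schedule of fixed-length bursts. During
#' its own bursts it oscillates across the contact point (a triangle wave of
#' speed `speed`, reversing every `osc_half_steps` steps); during the
#' partner's bursts it holds still. Roles alternate every `burst_steps` steps;
#' `role` fixes which burst parity the agent owns, so two agents constructed
#' with the same schedule parameters and complementary roles trade activity
#' and passivity exactly. After `n_exchanges` full exchanges the agent stops
#' and clicks (with a seeded jitter of up to `click_jitter_steps`); an agent
#' that never confirms contact never starts the schedule and never clicks.
#'
#' The schedule (onset, burst length, role) is agreed at construction, like
#' the conventions human pairs develop; at run time the agent still only
#' reads its own stimulation channel.
#'
#' @param burst_steps Length of one activity burst in steps.
#' @param seed Integer seed for the click jitter draw.
#' @param role 1 or 2: which burst parity this agent owns.
#' @param n_exchanges Number of completed exchanges before clicking.
#' @param start_delay_steps Steps to idle before monitoring for contact
#'   (shared by the pair to set the engagement onset).
#' @param confirm_steps Consecutive stimulated steps required to confirm
#'   sustained contact.
#' @param speed Oscillation speed in units/step while active (kept above the
#'   movement-binarization threshold so active steps register as movement).
#' @param osc_half_steps Steps between direction reversals of the triangle
#'   wave; `burst_steps` should be a multiple of `2 * osc_half_steps` so each
#'   burst ends where it began.
#' @param click_jitter_steps Maximum click jitter in steps after the final
#'   exchange completes.
#' @return An `agent_controller`.
#' @examples
#' p1 <- make_turn_taker_agent(role = 1, seed = 1)
#' p2 <- make_turn_taker_agent(role = 2, seed = 2)
#' @export
make_turn_taker_agent <- function(burst_steps = 250, seed = NULL, role = 1,
                                  n_exchanges = 2, start_delay_steps = 0,
                                  confirm_steps = 25, speed = 0.6,
                                  osc_half_steps = 25,
                                  click_jitter_steps = 80) {
  if (burst_steps < 1) stop("`burst_steps` must be at least 1.", call. = FALSE)
  if (!role %in% c(1, 2)) stop("`role` must be 1 or 2.", call. = FALSE)
  jitter <- if (is.null(seed) || click_jitter_steps == 0) {
    0L
  } else {
    with_local_seed(seed, sample.int(click_jitter_steps, 1))
  }
  total_alt <- 2L * n_exchanges * burst_steps
  init <- function() {
    list(engaged_at = NA_integer_, stim_run = 0L, clicked = FALSE)
  }
  move <- function(state, t, pos, stim) {
    state$stim_run <- if (stim) state$stim_run + 1L else 0L
    vel <- 0
    click <- FALSE
    if (is.na(state$engaged_at)) {
      if (t >= start_delay_steps && state$stim_run >= confirm_steps) {
        state$engaged_at <- t # engage and start the schedule this very step
      } else {
        return(list(vel = vel, click = click, state = state))
      }
    }
    phase <- t - state$engaged_at
    if (phase < total_alt) {
      cycle <- phase %/% burst_steps
      if (cycle %% 2L == (role - 1L)) {
        dir <- if (phase %% (2L * osc_half_steps) < osc_half_steps) 1 else -1
        vel <- dir * speed
      }
    } else if (!state$clicked && phase >= total_alt + jitter) {
      click <- TRUE
      state$clicked <- TRUE
    }
    list(vel = vel, click = click, state = state)
  }
  new_agent_controller(
    init, move,
    label = "turn_taker",
    params = list(
      burst_steps = burst_steps, role = role, n_exchanges = n_exchanges,
      start_delay_steps = start_delay_steps, seed = seed
    )
  )
}
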