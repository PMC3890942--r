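#' Binarize a movement trajectory
#'
#' Classifies each step of a position series as moving (1) or non-moving (0).
#' The per-step displacement `dx` is the absolute wrapped displacement
#' between consecutive positions; a step is raw-moving when
#' `dx > cfg$move_threshold` (strictly, with the default threshold an eighth
#' of the body length). Because players produce micro-pauses within a single
#' "turn", a raw non-moving step only becomes a final 0 when it lies in a run
#' of at least `cfg$min_pause_steps` consecutive raw-0 steps (500 ms at the
#' default rate); shorter pauses remain 1.
#'
#' The returned series has one element per displacement, i.e. length
#' `length(positions) - 1`; element `t` describes the movement arriving at
#' position `t + 1`.
#'
#' @param positions Wrapped position series (length at least 2).
#' @param cfg An [env_config()].
#' @return Integer vector of 0/1.
#' @examples
#' binarize_movement(c(0, 0.6, 1.2, 1.2, 1.8), env_config())
#' @export
binarize_movement <- function(positions, cfg = env_config()) {
  if (length(positions) < 2) {
    stop("Need at least 2 position samples to binarize movement.",
      call. = FALSE
    )
  }
  L <- cfg$space_length
  dx <- abs(signed_displacement(
    positions[-length(positions)], positions[-1], L
  ))
  raw <- as.integer(dx > cfg$move_threshold)
  r <- rle(raw)
  keep_zero <- r$values == 0L & r$lengths >= cfg$min_pause_steps
  r$values[!keep_zero] <- 1L
  inverse.rle(r)
}

#' Turn-taking score of two binary activity series
#'
#' Measures how well two players traded activity and passivity over a
#' window. With `D = B1 NAND B2`, the active contributions are
#' `C1 = sum(B1 & D)` and `C2 = sum(B2 & D)` — the numbers of steps on which
#' exactly one player moved — and the score is `TT = 4 * C1 * C2 / T^2` for a
#' window of `T` steps. `TT` lies in `[0, 1]`: 0 when there is no exchange
#' (e.g. both always moving, or only one ever moving) and 1 for a perfect
#' exchange in which each player is the sole mover for exactly half the
#' window.
#'
#' @param b1,b2 Equal-length 0/1 vectors.
#' @return A `tt_score` object: list with `tt`, `c1`, `c2`, `t_steps`.
#' @examples
#' turn_taking_score(c(1, 1, 1, 0, 0, 0), c(0, 0, 0, 0, 1, 1))
#' @export
turn_taking_score <- function(b1, b2) {
  if (length(b1) != length(b2)) {
    stop("`b1` and `b2` must have equal length.", call. = FALSE)
  }
  if (length(b1) < 1) stop("Series must be non-empty.", call. = FALSE)
  if (!all(b1 %in% c(0, 1)) || !all(b2 %in% c(0, 1))) {
    stop("Series must be binary (0/1).", call. = FALSE)
  }
  b1 <- as.integer(b1)
  b2 <- as.integer(b2)
  d <- 1L - (b1 & b2) # NAND
  c1 <- sum(b1 & d)
  c2 <- sum(b2 & d)
  t_steps <- length(b1)
  structure(
    list(
      tt = 4 * c1 * c2 / t_steps^2,
      c1 = c1, c2 = c2, t_steps = t_steps
    ),
    class = "tt_score"
  )
}

#' @export
print.tt_score <- function(x, ...) {
  cat(sprintf(
    "<tt_score: TT = %.3f (C1 = %d, C2 = %d, T = %d)>\n",
    x$tt, x$c1, x$c2, x$t_steps
  ))
  invisible(x)
}

#' Turn-taking before a click
#'
#' Binarizes both players' full-trial movement (so pause merging sees the
#' whole trajectory) and scores turn-taking over the window of
#' `cfg$tt_window` seconds preceding the click. The window is half-open at
#' the click — it covers the displacements arriving at steps
#' `click_step - W + 1, ..., click_step` — and is truncated to the available
#' steps for clicks earlier than a full window into the trial, with `T` set
#' to the actual window length as the score's normalizer.
#'
#' @param rec A `trial_recording`.
#' @param player 1 or 2 (the clicking player; the score itself is symmetric
#'   in the two players).
#' @param click_step 0-based step of the click; must be at least 1.
#' @param cfg Configuration; defaults to the recording's.
#' @return A `tt_score`.
#' @export
tt_before_click <- function(rec, player, click_step, cfg = rec$cfg) {
  if (click_step < 1) {
    stop("Turn-taking window undefined for a click at step 0.", call. = FALSE)
  }
  m1 <- binarize_movement(rec$steps$pos1, cfg)
  m2 <- binarize_movement(rec$steps$pos2, cfg)
  window_steps <- round(cfg$tt_window * 1000 / cfg$sample_period)
  w <- min(window_steps, click_step)
  idx <- (click_step - w + 1):click_step # movement-series indices (1-based)
  turn_taking_score(m1[idx], m2[idx])
}

#' Per-click turn-taking table for a dataset
#'
#' @param ds A `pc_dataset`.
#' @return A tibble with one row per retained click: team, trial, player,
#'   click_time_ms, tt, c1, c2, t_steps.
#' @export
tt_table <- function(ds) {
  rows <- purrr::map_dfr(ds$recordings, function(rec) {
    cl <- rec$clicks
    if (nrow(cl) == 0) {
      return(NULL)
    }
    purrr::map_dfr(seq_len(nrow(cl)), function(j) {
      s <- tt_before_click(rec, cl$player[j], cl$step[j])
      tibble::tibble(
        team = rec$meta$team %||% 1L, trial = rec$meta$trial %||% 1L,
        player = cl$player[j], click_time_ms = cl$time_ms[j],
        tt = s$tt, c1 = s$c1, c2 = s$c2, t_steps = s$t_steps
      )
    })
  })
  if (nrow(rows) == 0) {
    rows <- tibble::tibble(
      team = integer(), trial = integer(), player = integer(),
      click_time_ms = numeric(), tt = numeric(), c1 = integer(),
      c2 = integer(), t_steps = integer()
    )
  }
  rows
}
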