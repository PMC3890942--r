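#' Segment a stimulation series into contacts
#'
#' A player's *contact* is a maximal run of uninterrupted tactile
#' stimulation. Each object type (other's avatar, other's shadow, own static
#' object) that overlaps the player's avatar at any step inside the run
#' contributes to the contact, and is counted once per contact no matter how
#' many separate times it re-enters during the run. This reflects the
#' player's first-person perspective: one unbroken vibration is one event.
#'
#' @param stim Logical (or 0/1) vector: per-step stimulation.
#' @param overlaps Data frame with logical columns `avatar`, `shadow`,
#'   `static`, one row per step: the per-object overlap indicators. Their
#'   row-wise OR must reproduce `stim` exactly.
#' @return A tibble with one row per contact: `start` and `end` (0-based step
#'   indices, half-open `[start, end)`), and logical columns `avatar`,
#'   `shadow`, `static` marking the object types involved.
#' @examples
#' stim <- c(1, 1, 0, 1)
#' ov <- tibble::tibble(
#'   avatar = c(TRUE, FALSE, FALSE, FALSE),
#'   shadow = c(FALSE, FALSE, FALSE, TRUE),
#'   static = c(FALSE, TRUE, FALSE, FALSE)
#' )
#' segment_contacts(stim, ov)
#' @export
segment_contacts <- function(stim, overlaps) {
  stim <- as.logical(stim)
  overlaps <- tibble::as_tibble(overlaps)
  req <- c("avatar", "shadow", "static")
  if (!all(req %in% names(overlaps))) {
    stop("`overlaps` must have columns avatar, shadow, static.", call. = FALSE)
  }
  if (nrow(overlaps) != length(stim)) {
    stop("`stim` and `overlaps` must have the same length.", call. = FALSE)
  }
  any_ov <- overlaps$avatar | overlaps$shadow | overlaps$static
  if (!identical(as.logical(any_ov), stim)) {
    stop("`stim` is inconsistent with `overlaps`: it must equal their row-wise OR.",
      call. = FALSE
    )
  }
  if (length(stim) == 0 || !any(stim)) {
    return(tibble::tibble(
      contact = integer(), start = integer(), end = integer(),
      avatar = logical(), shadow = logical(), static = logical()
    ))
  }
  r <- rle(stim)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  tibble::tibble(
    contact = seq_along(on),
    start = starts[on] - 1L, # 0-based, half-open [start, end)
    end = ends[on],
    avatar = vapply(on, function(i) any(overlaps$avatar[starts[i]:ends[i]]), logical(1)),
    shadow = vapply(on, function(i) any(overlaps$shadow[starts[i]:ends[i]]), logical(1)),
    static = vapply(on, function(i) any(overlaps$static[starts[i]:ends[i]]), logical(1))
  )
}

#' Contacts of one player in a trial recording
#'
#' Applies [segment_contacts()] to a player's recorded stimulation and the
#' overlap channels recomputed from positions, and adds player and time
#' columns.
#'
#' @param rec A `trial_recording`.
#' @param player 1 or 2.
#' @return A tibble of contacts with `player`, `start_ms`, `end_ms` added.
#' @export
contacts <- function(rec, player) {
  ct <- segment_contacts(player_stim(rec, player), overlap_channels(rec, player))
  ct$player <- as.integer(player)
  ct$start_ms <- ct$start * rec$cfg$sample_period
  ct$end_ms <- ct$end * rec$cfg$sample_period
  ct
}

#' Count contacts by object type
#'
#' One contact can involve several object types and then increments several
#' counters, so the per-type counts can exceed the number of contacts.
#'
#' @param contact_tbl A tibble as returned by [segment_contacts()] (logical
#'   columns `avatar`, `shadow`, `static`).
#' @return A tibble with columns `type` and `n_contacts`.
#' @examples
#' count_contacts_by_type(contact_example_contacts())
#' @export
count_contacts_by_type <- function(contact_tbl) {
  tibble::tibble(
    type = c("avatar", "shadow", "static"),
    n_contacts = c(
      sum(contact_tbl$avatar), sum(contact_tbl$shadow),
      sum(contact_tbl$static)
    )
  )
}

#' Attribute a click to its intended target
#'
#' Positions are sampled `cfg$click_lookback` seconds before the click
#' (clamped to the trial start for very early clicks). If the other player's
#' avatar lies within the attribution range (absolute wrapped displacement at
#' most `cfg$target_range`) the click targets the avatar; otherwise the
#' other's shadow is tried, then the player's own static object; otherwise
#' the click has no identifiable target (`"none"`). The avatar and its shadow
#' can never both be in range because twice the range is smaller than the
#' rigid avatar-shadow offset.
#'
#' @param rec A `trial_recording`.
#' @param player 1 or 2 (the clicking player).
#' @param click_step 0-based step index of the click.
#' @return One of `"avatar"`, `"shadow"`, `"static"`, `"none"`.
#' @export
assign_click_target <- function(rec, player, click_step) {
  cfg <- rec$cfg
  n <- nrow(rec$steps)
  if (click_step < 0 || click_step >= n) {
    stop("`click_step` outside the trial.", call. = FALSE)
  }
  lookback_steps <- round(cfg$click_lookback * 1000 / cfg$sample_period)
  lb <- max(0L, as.integer(click_step) - lookback_steps)
  i <- lb + 1L
  own <- player_positions(rec, player)[i]
  other <- player_positions(rec, 3 - player)[i]
  other_shadow <- shadow_positions(rec, 3 - player)[i]
  own_static <- rec$static_pos[player]
  in_range <- function(x) {
    abs(signed_displacement(own, x, cfg$space_length)) <= cfg$target_range
  }
  if (in_range(other)) {
    "avatar"
  } else if (in_range(other_shadow)) {
    "shadow"
  } else if (in_range(own_static)) {
    "static"
  } else {
    "none"
  }
}

#' Attribute every retained click of a recording or dataset
#'
#' @param x A `trial_recording` or `pc_dataset`.
#' @return A tibble with one row per retained click: `team`, `trial`,
#'   `player`, `click_step`, `click_time_ms`, `target` (and, for datasets,
#'   the generator's `scenario` and `true_target` columns joined in).
#' @export
attribute_clicks <- function(x) {
  UseMethod("attribute_clicks")
}

#' @export
attribute_clicks.trial_recording <- function(x) {
  cl <- x$clicks
  tibble::tibble(
    team = x$meta$team %||% 1L,
    trial = x$meta$trial %||% 1L,
    player = cl$player,
    click_step = cl$step,
    click_time_ms = cl$time_ms,
    target = vapply(
      seq_len(nrow(cl)),
      function(j) assign_click_target(x, cl$player[j], cl$step[j]),
      character(1)
    )
  )
}

#' @export
attribute_clicks.pc_dataset <- function(x) {
  out <- purrr::map_dfr(x$recordings, attribute_clicks)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      team = integer(), trial = integer(), player = integer(),
      click_step = integer(), click_time_ms = numeric(), target = character()
    ))
  }
  dplyr::left_join(
    out,
    x$truth[, c("team", "trial", "player", "scenario", "true_target")],
    by = c("team", "trial", "player")
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
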