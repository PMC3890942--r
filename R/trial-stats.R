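#' Classify a trial from its two attributed clicks
#'
#' A trial is a *Joint Success* when both players' retained clicks targeted
#' the other's avatar; a *Single Success* when exactly one click did (the
#' other player clicking wrongly or not at all); *WrongOnly* when there were
#' clicks but none on the avatar; and *NoClicks* when neither player
#' clicked. Any click whose target is not the avatar (shadow, static, or no
#' identifiable target) is a wrong click.
#'
#' @param targets Character vector of length 0, 1 or 2: the attributed
#'   targets of the trial's retained clicks.
#' @return One of `"JointSuccess"`, `"SingleSuccess"`, `"WrongOnly"`,
#'   `"NoClicks"`.
#' @examples
#' classify_trial(c("avatar", "avatar"))
#' classify_trial(c("avatar"))
#' classify_trial(character(0))
#' @export
classify_trial <- function(targets) {
  if (length(targets) > 2) {
    stop("At most one retained click per player: got ", length(targets),
      " clicks.",
      call. = FALSE
    )
  }
  n_correct <- sum(targets == "avatar")
  if (length(targets) == 0) {
    "NoClicks"
  } else if (n_correct == 2) {
    "JointSuccess"
  } else if (n_correct == 1) {
    "SingleSuccess"
  } else {
    "WrongOnly"
  }
}

#' Classify every click and trial of an attributed click table
#'
#' `classify_clicks()` adds a `click_category` column (`joint_success`,
#' `single_success`, `wrong`) to a click table; `classify_trials()` returns
#' one row per trial with the trial-level outcome. Trials listed in
#' `all_trials` but absent from `click_tbl` are reported as `NoClicks`.
#'
#' @param click_tbl Tibble with columns `team`, `trial`, `player`, `target`
#'   (as from [attribute_clicks()]).
#' @param all_trials Optional tibble with columns `team`, `trial` listing
#'   every trial run (defaults to the trials present in `click_tbl`).
#' @return A tibble.
#' @export
classify_clicks <- function(click_tbl) {
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(click_tbl, .data$team, .data$trial),
    click_category = dplyr::case_when(
      .data$target == "avatar" & sum(.data$target == "avatar") == 2 ~
        "joint_success",
      .data$target == "avatar" ~ "single_success",
      TRUE ~ "wrong"
    )
  ))
}

#' @rdname classify_clicks
#' @export
classify_trials <- function(click_tbl, all_trials = NULL) {
  per_trial <- dplyr::summarise(
    dplyr::group_by(click_tbl, .data$team, .data$trial),
    outcome = classify_trial(.data$target),
    .groups = "drop"
  )
  if (!is.null(all_trials)) {
    per_trial <- dplyr::left_join(
      dplyr::distinct(all_trials[, c("team", "trial")]),
      per_trial,
      by = c("team", "trial")
    )
    per_trial$outcome[is.na(per_trial$outcome)] <- "NoClicks"
  }
  tibble::as_tibble(per_trial)
}

#' Team score under the tournament rule
#'
#' A team gains one point for every click that correctly identified the
#' other's avatar and loses one point for every wrong click (any other
#' target, including clicks with no identifiable target). Absent clicks
#' contribute nothing.
#'
#' @param targets Character vector of attributed click targets for one team
#'   across all its trials.
#' @return Integer score.
#' @examples
#' team_score(rep("avatar", 30)) # perfect 15-trial tournament
#' @export
team_score <- function(targets) {
  as.integer(sum(targets == "avatar") - sum(targets != "avatar"))
}

#' @rdname team_score
#' @param click_tbl Attributed click table with `team` and `target` columns.
#' @return `team_scores()`: tibble with `team` and `score`.
#' @export
team_scores <- function(click_tbl) {
  dplyr::summarise(
    dplyr::group_by(click_tbl, .data$team),
    score = team_score(.data$target),
    .groups = "drop"
  )
}

#' Clicking accuracy of one player
#'
#' The percentage of a player's clicks that targeted the other's avatar.
#' Undefined (`NA`) for a player who never clicked — not 0.
#'
#' @param targets Character vector of a player's attributed click targets.
#' @return Percentage in `[0, 100]`, or `NA_real_` for zero clicks.
#' @examples
#' clicking_accuracy(c(rep("avatar", 12), "shadow")) # 92.3
#' @export
clicking_accuracy <- function(targets) {
  if (length(targets) == 0) {
    return(NA_real_)
  }
  100 * sum(targets == "avatar") / length(targets)
}

#' @rdname clicking_accuracy
#' @param click_tbl Attributed click table with `team`, `player`, `target`.
#' @return `clicking_accuracies()`: tibble with `team`, `player`, `n_clicks`,
#'   `accuracy`.
#' @export
clicking_accuracies <- function(click_tbl) {
  dplyr::summarise(
    dplyr::group_by(click_tbl, .data$team, .data$player),
    n_clicks = dplyr::n(),
    accuracy = clicking_accuracy(.data$target),
    .groups = "drop"
  )
}

#' Probability of a click following a single contact, per object type
#'
#' Divides the number of clicks attributed to each object type by the number
#' of contacts with that type, expressed as a percentage.
#'
#' @param clicks_by_type,contacts_by_type Named numeric vectors (names
#'   `avatar`, `shadow`, `static`) or tibbles with columns `type` and a
#'   count column (`n_clicks` / `n_contacts`).
#' @return A tibble with columns `type`, `clicks`, `contacts`,
#'   `probability` (percent).
#' @examples
#' click_probability_per_contact(
#'   c(avatar = 338, shadow = 33, static = 11),
#'   c(avatar = 28996, shadow = 5046, static = 5621)
#' )
#' @export
click_probability_per_contact <- function(clicks_by_type, contacts_by_type) {
  as_named <- function(x, count_col) {
    if (is.data.frame(x)) {
      stats::setNames(x[[count_col]], x$type)
    } else {
      x
    }
  }
  clicks <- as_named(clicks_by_type, "n_clicks")
  contacts <- as_named(contacts_by_type, "n_contacts")
  types <- intersect(names(contacts), names(clicks))
  if (length(types) == 0) {
    stop("No common object types between clicks and contacts.", call. = FALSE)
  }
  clicks <- clicks[types]
  contacts <- contacts[types]
  if (any(contacts == 0 & clicks > 0)) {
    stop("Inconsistent counts: clicks reported for a type with zero contacts.",
      call. = FALSE
    )
  }
  tibble::tibble(
    type = types,
    clicks = as.numeric(clicks),
    contacts = as.numeric(contacts),
    probability = ifelse(contacts > 0, 100 * clicks / contacts, NA_real_)
  )
}

#' Relative frequency of ratings by click category
#'
#' Tabulates a 4-level rating scale (Perceptual Awareness Scale or
#' Confidence Rating) within the click categories Joint Success, Single
#' Success and Wrong Click. Frequencies within a category are relative to
#' the rated clicks of that category and sum to 1; absent ratings are
#' excluded from the frequencies and reported in `n_missing`. A category
#' with no rated clicks is kept as an all-zero row with `empty = TRUE`.
#'
#' @param questionnaires Tibble with columns `team`, `trial`, `player` and
#'   the rating column named by `scale` (integer 1-4 or `NA`).
#' @param click_tbl Click table with `click_category` (see
#'   [classify_clicks()]).
#' @param scale Name of the rating column, `"pas"` or `"cr"`.
#' @return A tibble with one row per category x level: `category`, `level`,
#'   `n`, `freq`, `n_rated`, `n_missing`, `empty`.
#' @export
rating_frequency_table <- function(questionnaires, click_tbl,
                                   scale = c("pas", "cr")) {
  scale <- match.arg(scale)
  joined <- dplyr::inner_join(
    click_tbl[, c("team", "trial", "player", "click_category")],
    questionnaires[, c("team", "trial", "player", scale)],
    by = c("team", "trial", "player")
  )
  orphan <- dplyr::anti_join(
    questionnaires[
      !is.na(questionnaires[[scale]]),
      c("team", "trial", "player")
    ],
    click_tbl[, c("team", "trial", "player")],
    by = c("team", "trial", "player")
  )
  if (nrow(orphan) > 0) {
    warning(nrow(orphan), " rating(s) present without a matching click; ignored.",
      call. = FALSE
    )
  }
  cats <- c(
    joint_success = "JointSuccess", single_success = "SingleSuccess",
    wrong = "WrongClick"
  )
  out <- purrr::map_dfr(names(cats), function(cc) {
    vals <- joined[[scale]][joined$click_category == cc]
    n_missing <- sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    counts <- vapply(1:4, function(l) sum(vals == l), numeric(1))
    tibble::tibble(
      category = cats[[cc]],
      level = 1:4,
      n = counts,
      freq = if (length(vals) > 0) counts / length(vals) else rep(0, 4),
      n_rated = length(vals),
      n_missing = n_missing,
      empty = length(vals) == 0
    )
  })
  out
}
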