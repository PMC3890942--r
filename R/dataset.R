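#' Generate a synthetic perceptual-crossing dataset
#'
#' Produces a full tournament-style dataset — `n_teams` pairs, `n_trials`
#' one-minute trials each — from scripted agent controllers, together with a
#' ground-truth table of click targets and synthetic post-trial
#' questionnaires. Scenarios:
#'
#' * `"turn_takers"`: every pair starts in mutual avatar contact and runs the
#'   coordinated burst-alternation script of [make_turn_taker_agent()], with
#'   a per-trial engagement onset; both players click shortly after
#'   completing their exchanges, so clicks are near-synchronous within a
#'   trial but spread across trials.
#' * `"scanners"`: every pair consists of two independent sweepers
#'   ([make_scanner_agent()]) with seeded speeds, spans and arming times;
#'   clicks land on whatever object the sweep happens to touch.
#' * `"mixed"`: odd-numbered teams are turn-taker pairs, even-numbered teams
#'   scanner pairs.
#' * `"stationary"`: both players immobile and out of contact; no clicks.
#'
#' The ground-truth target of each click is computed from the simulator's
#' full state at the click-lookback instant (the object, in priority order
#' avatar > shadow > static, whose wrapped displacement from the clicking
#' avatar is within `cfg$target_range`), so every analysis stage can be
#' scored against it. Questionnaire ratings are drawn from click context:
#' jointly correct clicks draw high awareness/confidence levels, solo correct
#' clicks intermediate ones, wrong clicks low ones.
#'
#' @param n_teams,n_trials Positive counts.
#' @param scenario Scenario name (see above).
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   arguments and this seed.
#' @param cfg An [env_config()].
#' @return A `pc_dataset`: list with `cfg`, `recordings` (list of
#'   [trial recordings][simulate_trial], one per team x trial), `truth`
#'   (tibble: team, trial, player, scenario, click_step, click_time_ms,
#'   true_target), `questionnaires` (tibble: team, trial, player, clicked,
#'   pas, cr, free_text), plus the generating arguments.
#' @examples
#' ds <- generate_dataset(1, 2, scenario = "turn_takers", seed = 7)
#' ds$truth
#' @export
generate_dataset <- function(n_teams, n_trials,
                             scenario = c(
                               "mixed", "turn_takers", "scanners",
                               "stationary"
                             ),
                             seed = 1, cfg = env_config()) {
  scenario <- match.arg(scenario)
  stopifnot(n_teams >= 1, n_trials >= 1)
  L <- cfg$space_length
  n <- n_steps(cfg)
  lookback_steps <- round(cfg$click_lookback * 1000 / cfg$sample_period)

  team_scenario <- switch(scenario,
    mixed = ifelse(seq_len(n_teams) %% 2 == 1, "turn_takers", "scanners"),
    rep(scenario, n_teams)
  )

  with_local_seed(seed, {
    params <- tidyr::expand_grid(
      team = seq_len(n_teams),
      trial = seq_len(n_trials)
    )
    params$scenario <- team_scenario[params$team]
    m <- nrow(params)
    params$start1 <- stats::runif(m, 0, L)
    params$start2 <- stats::runif(m, 0, L)
    params$delay <- sample(200:4700, m, replace = TRUE)
    params$seed1 <- sample.int(.Machine$integer.max - 1L, m)
    params$seed2 <- sample.int(.Machine$integer.max - 1L, m)
    params$speed1 <- stats::runif(m, 0.55, 0.9)
    params$speed2 <- stats::runif(m, 0.55, 0.9)
    params$span1 <- stats::runif(m, 120, 500)
    params$span2 <- stats::runif(m, 120, 500)

    recordings <- vector("list", m)
    truth_rows <- vector("list", m)
    for (k in seq_len(m)) {
      pk <- params[k, ]
      if (pk$scenario == "turn_takers") {
        starts <- wrap_position(c(pk$start1, pk$start1 + 2), L)
        ctrls <- list(
          make_turn_taker_agent(
            role = 1, seed = pk$seed1,
            start_delay_steps = pk$delay
          ),
          make_turn_taker_agent(
            role = 2, seed = pk$seed2,
            start_delay_steps = pk$delay
          )
        )
        clearance <- 40
      } else if (pk$scenario == "scanners") {
        starts <- wrap_position(c(pk$start1, pk$start2), L)
        ctrls <- list(
          make_scanner_agent(
            speed = pk$speed1, span = pk$span1,
            seed = pk$seed1, sample_period = cfg$sample_period
          ),
          make_scanner_agent(
            speed = pk$speed2, span = pk$span2,
            seed = pk$seed2, sample_period = cfg$sample_period
          )
        )
        clearance <- 2 * cfg$body_length
      } else { # stationary
        starts <- wrap_position(c(pk$start1, pk$start1 + L / 2), L)
        ctrls <- list(make_stationary_agent(), make_stationary_agent())
        clearance <- 2 * cfg$body_length
      }
      static_pos <- c(NA_real_, NA_real_)
      for (p in 1:2) {
        repeat {
          cand <- stats::runif(1, 0, L)
          if (all(abs(signed_displacement(starts, cand, L)) >= clearance)) {
            static_pos[p] <- cand
            break
          }
        }
      }
      rec <- simulate_trial(
        ctrls, cfg,
        seed = NULL, starts = starts, static_pos = static_pos,
        meta = list(team = pk$team, trial = pk$trial, scenario = pk$scenario)
      )
      recordings[[k]] <- rec
      if (nrow(rec$clicks) > 0) {
        tt <- rec$clicks
        tt$true_target <- vapply(seq_len(nrow(tt)), function(j) {
          pl <- tt$player[j]
          lb <- max(0L, tt$step[j] - lookback_steps) + 1L # 1-based row index
          own <- if (pl == 1) rec$steps$pos1[lb] else rec$steps$pos2[lb]
          other <- if (pl == 1) rec$steps$pos2[lb] else rec$steps$pos1[lb]
          osh <- wrap_position(other + rec$meta$shadow_sign * cfg$shadow_offset, L)
          near <- function(x) {
            abs(signed_displacement(own, x, L)) <= cfg$target_range
          }
          if (near(other)) {
            "avatar"
          } else if (near(osh)) {
            "shadow"
          } else if (near(static_pos[pl])) {
            "static"
          } else {
            "none"
          }
        }, character(1))
        tt$team <- pk$team
        tt$trial <- pk$trial
        tt$scenario <- pk$scenario
        truth_rows[[k]] <- tt
      }
    }
    truth <- dplyr::bind_rows(truth_rows)
    if (nrow(truth) == 0) {
      truth <- tibble::tibble(
        team = integer(), trial = integer(), player = integer(),
        scenario = character(), click_step = integer(),
        click_time_ms = numeric(), true_target = character()
      )
    } else {
      truth <- dplyr::select(
        dplyr::rename(truth, click_step = "step", click_time_ms = "time_ms"),
        "team", "trial", "player", "scenario", "click_step",
        "click_time_ms", "true_target"
      )
    }
    questionnaires <- synth_questionnaires(truth, n_teams, n_trials)

    structure(
      list(
        cfg = cfg, recordings = recordings, truth = truth,
        questionnaires = questionnaires, scenario = scenario,
        n_teams = n_teams, n_trials = n_trials, seed = seed
      ),
      class = "pc_dataset"
    )
  })
}

# Ratings drawn from click context: joint-success clicks report the clearest
# awareness and the highest confidence most often, wrong clicks the least.
synth_questionnaires <- function(truth, n_teams, n_trials) {
  grid <- tidyr::expand_grid(
    team = seq_len(n_teams), trial = seq_len(n_trials), player = 1:2
  )
  q <- dplyr::left_join(grid, truth, by = c("team", "trial", "player"))
  q$clicked <- !is.na(q$true_target)
  q <- dplyr::mutate(
    dplyr::group_by(q, .data$team, .data$trial),
    .n_correct = sum(.data$clicked & .data$true_target == "avatar",
      na.rm = TRUE
    )
  )
  q <- dplyr::ungroup(q)
  correct <- q$clicked & !is.na(q$true_target) & q$true_target == "avatar"
  category <- dplyr::case_when(
    !q$clicked ~ NA_character_,
    correct & q$.n_correct == 2 ~ "joint",
    correct ~ "single",
    TRUE ~ "wrong"
  )
  draw <- function(cat) {
    switch(cat,
      joint = sample(c(4L, 3L), 1, prob = c(0.7, 0.3)),
      single = sample(c(4L, 3L, 2L), 1, prob = c(0.15, 0.55, 0.3)),
      wrong = sample(c(3L, 2L, 1L), 1, prob = c(0.3, 0.5, 0.2))
    )
  }
  texts <- c(
    joint = "clear sense of the other; we found each other",
    single = "thought it was the partner, but less certain",
    wrong = "hard to tell whether it was the partner or an object"
  )
  q$pas <- NA_integer_
  q$cr <- NA_integer_
  q$free_text <- NA_character_
  for (i in seq_len(nrow(q))) {
    if (!is.na(category[i])) {
      q$pas[i] <- draw(category[i])
      q$cr[i] <- draw(category[i])
      q$free_text[i] <- texts[[category[i]]]
    }
  }
  tibble::as_tibble(
    q[, c("team", "trial", "player", "clicked", "pas", "cr", "free_text")]
  )
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat(sprintf(
    "<pc_dataset: %d team(s) x %d trial(s), scenario '%s', %d click(s), seed %s>\n",
    x$n_teams, x$n_trials, x$scenario, nrow(x$truth), format(x$seed)
  ))
  invisible(x)
}
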