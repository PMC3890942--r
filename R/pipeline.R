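#' Run the full analysis pipeline
#'
#' Orchestrates every analysis stage on a dataset of trial recordings:
#' contact segmentation and per-type counts, click-target attribution,
#' trial/click classification, team scores and clicking accuracies,
#' per-contact click probabilities, turn-taking before each click,
#' rating-frequency tables, the variance-gated group comparisons (TT and PAS
#' across Joint Success / Single Success / Wrong Click categories), and the
#' click-synchrony randomization analysis. The report is a pure function of
#' the input dataset (or generating scenario plus seed) and the
#' configuration.
#'
#' @param input A `pc_dataset`, a directory containing trial logs written by
#'   [write_dataset()], or a scenario name accepted by [generate_dataset()].
#' @param cfg An [env_config()] (used when generating).
#' @param seed Integer seed (used when generating).
#' @param n_teams,n_trials Dataset size (used when generating).
#' @param out_dir Optional directory: when given, all tables are written as
#'   CSV together with a JSON run manifest carrying file checksums.
#' @return A `pc_report` (list of tibbles and fitted objects).
#' @examples
#' rep <- run_pipeline("turn_takers", n_teams = 1, n_trials = 3, seed = 2)
#' rep$scores
#' @export
run_pipeline <- function(input, cfg = env_config(), seed = 1,
                         n_teams = 17, n_trials = 15, out_dir = NULL) {
  ds <- if (inherits(input, "pc_dataset")) {
    input
  } else if (is.character(input) && length(input) == 1 && dir.exists(input)) {
    read_dataset(input)
  } else if (is.character(input) && length(input) == 1) {
    generate_dataset(n_teams, n_trials, scenario = input, seed = seed, cfg = cfg)
  } else {
    stop("`input` must be a pc_dataset, a directory, or a scenario name.",
      call. = FALSE
    )
  }
  warnings <- character(0)
  stage <- function(name, rec_id, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed (%s): %s", name, rec_id,
        conditionMessage(e)),
      call. = FALSE
      )
    })
  }

  contact_tbl <- purrr::map_dfr(ds$recordings, function(rec) {
    id <- sprintf("team %s trial %s", rec$meta$team, rec$meta$trial)
    stage("contacts", id, {
      both <- dplyr::bind_rows(contacts(rec, 1), contacts(rec, 2))
      if (nrow(both) > 0) {
        both$team <- rec$meta$team
        both$trial <- rec$meta$trial
      }
      both
    })
  })
  contact_counts <- if (nrow(contact_tbl) > 0) {
    count_contacts_by_type(contact_tbl)
  } else {
    tibble::tibble(
      type = c("avatar", "shadow", "static"),
      n_contacts = c(0, 0, 0)
    )
  }

  clicks <- stage("attribution", "all trials", attribute_clicks(ds))
  clicks <- if (nrow(clicks) > 0) classify_clicks(clicks) else clicks
  ttab <- stage("turn-taking", "all trials", tt_table(ds))
  if (nrow(clicks) > 0) {
    clicks <- dplyr::left_join(
      clicks, ttab[, c("team", "trial", "player", "tt")],
      by = c("team", "trial", "player")
    )
  }

  all_trials <- tidyr::expand_grid(
    team = seq_len(ds$n_teams), trial = seq_len(ds$n_trials)
  )
  outcomes <- classify_trials(clicks, all_trials)
  scores <- if (nrow(clicks) > 0) {
    dplyr::left_join(
      tibble::tibble(team = seq_len(ds$n_teams)),
      team_scores(clicks),
      by = "team"
    )
  } else {
    tibble::tibble(team = seq_len(ds$n_teams), score = NA_integer_)
  }
  scores$score[is.na(scores$score)] <- 0L
  accuracies <- if (nrow(clicks) > 0) {
    clicking_accuracies(clicks)
  } else {
    tibble::tibble(
      team = integer(), player = integer(),
      n_clicks = integer(), accuracy = numeric()
    )
  }

  clicks_by_type <- if (nrow(clicks) > 0) {
    c(
      avatar = sum(clicks$target == "avatar"),
      shadow = sum(clicks$target == "shadow"),
      static = sum(clicks$target == "static")
    )
  } else {
    c(avatar = 0, shadow = 0, static = 0)
  }
  contacts_by_type <- stats::setNames(
    contact_counts$n_contacts, contact_counts$type
  )[c("avatar", "shadow", "static")]
  probabilities <- if (any(contacts_by_type > 0)) {
    click_probability_per_contact(clicks_by_type, contacts_by_type)
  } else {
    NULL
  }

  has_ratings <- nrow(ds$questionnaires) > 0 && nrow(clicks) > 0
  pas_table <- if (has_ratings) {
    rating_frequency_table(ds$questionnaires, clicks, "pas")
  }
  cr_table <- if (has_ratings) {
    rating_frequency_table(ds$questionnaires, clicks, "cr")
  }

  gated <- pipeline_gated_tests(clicks, ds$questionnaires)

  synchrony <- NULL
  if (nrow(clicks) > 0) {
    jt <- joint_click_times(clicks)
    if (nrow(jt) >= 2) synchrony <- synchrony_analysis(jt)
  }

  report <- structure(
    list(
      dataset = ds,
      contact_tbl = contact_tbl,
      contact_counts = contact_counts,
      clicks = clicks,
      outcomes = outcomes,
      outcome_counts = dplyr::count(outcomes, .data$outcome, name = "n_trials"),
      scores = scores,
      accuracies = accuracies,
      probabilities = probabilities,
      pas_table = pas_table,
      cr_table = cr_table,
      gated_tests = gated,
      synchrony = synchrony,
      manifest = list(
        config = unclass(ds$cfg),
        scenario = ds$scenario,
        seed = ds$seed,
        version = as.character(utils::packageVersion("pcrossing")),
        row_counts = list(
          trials = length(ds$recordings),
          contacts = nrow(contact_tbl),
          clicks = nrow(clicks)
        ),
        warnings = warnings,
        outputs = list()
      )
    ),
    class = "pc_report"
  )
  if (!is.null(out_dir)) report <- write_report(report, out_dir)
  report
}

# The comparisons reported by the analysis: turn-taking and PAS across click
# categories (direction: the first-named group is hypothesized larger).
pipeline_gated_tests <- function(clicks, questionnaires) {
  if (nrow(clicks) == 0) {
    return(list(tests = list(), table = tibble::tibble()))
  }
  cl <- clicks
  if (nrow(questionnaires) > 0) {
    cl <- dplyr::left_join(
      cl, questionnaires[, c("team", "trial", "player", "pas", "cr")],
      by = c("team", "trial", "player")
    )
  }
  groups <- function(var) {
    list(
      joint = cl[[var]][cl$click_category == "joint_success"],
      single = cl[[var]][cl$click_category == "single_success"],
      wrong = cl[[var]][cl$click_category == "wrong"]
    )
  }
  specs <- list(
    list(var = "tt", a = "joint", b = "single"),
    list(var = "tt", a = "joint", b = "wrong"),
    list(var = "tt", a = "single", b = "wrong"),
    list(var = "pas", a = "joint", b = "single"),
    list(var = "pas", a = "joint", b = "wrong"),
    list(var = "pas", a = "single", b = "wrong")
  )
  tests <- list()
  for (sp in specs) {
    if (!sp$var %in% names(cl)) next
    g <- groups(sp$var)
    x <- g[[sp$a]][!is.na(g[[sp$a]])]
    y <- g[[sp$b]][!is.na(g[[sp$b]])]
    nm <- sprintf("%s_%s_vs_%s", sp$var, sp$a, sp$b)
    tests[[nm]] <- tryCatch(
      gated_comparison(x, y,
        direction = "x",
        labels = c(sp$a, sp$b)
      ),
      error = function(e) NULL
    )
  }
  tests <- tests[!vapply(tests, is.null, logical(1))]
  table <- purrr::map_dfr(names(tests), function(nm) {
    dplyr::mutate(tidy(tests[[nm]]), comparison = nm, .before = 1)
  })
  list(tests = tests, table = table)
}

#' @export
print.pc_report <- function(x, ...) {
  cat("<pc_report>\n")
  cat(
    sprintf(
      "  %d trial(s), %d contact(s), %d click(s)\n",
      x$manifest$row_counts$trials, x$manifest$row_counts$contacts,
      x$manifest$row_counts$clicks
    )
  )
  print(x$outcome_counts)
  if (!is.null(x$probabilities)) print(x$probabilities)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits every table of a [run_pipeline()] report as CSV plus a
#' human-readable stats report and a JSON manifest with md5 checksums of
#' every written file. Rerunning the pipeline with the same inputs and seed
#' writes byte-identical outputs.
#'
#' @param report A `pc_report`.
#' @param out_dir Output directory (created if needed).
#' @return The report, with `manifest$outputs` filled in, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(tbl, name) {
    if (is.null(tbl) || (is.data.frame(tbl) && nrow(tbl) == 0)) {
      return(invisible(NULL))
    }
    p <- file.path(out_dir, name)
    readr::write_csv(tbl, p)
    files <<- c(files, p)
  }
  emit(report$contact_tbl, "contacts.csv")
  emit(report$clicks, "clicks.csv")
  emit(report$contact_counts, "contact_counts.csv")
  emit(report$outcomes, "outcomes.csv")
  emit(report$scores, "scores.csv")
  emit(report$accuracies, "accuracies.csv")
  emit(report$probabilities, "click_probabilities.csv")
  emit(report$pas_table, "pas_table.csv")
  emit(report$cr_table, "cr_table.csv")
  emit(report$gated_tests$table, "gated_tests.csv")
  if (!is.null(report$synchrony)) {
    emit(report$synchrony$histogram, "synchrony_histogram.csv")
  }
  txt <- file.path(out_dir, "stats_report.txt")
  con <- file(txt, open = "wt")
  on.exit(close(con), add = TRUE)
  sink(con)
  print(report)
  for (g in report$gated_tests$tests) print(g)
  if (!is.null(report$synchrony)) print(report$synchrony)
  sink()
  files <- c(files, txt)
  report$manifest$outputs <- lapply(stats::setNames(files, basename(files)),
    function(p) list(md5 = unname(tools::md5sum(p)))
  )
  jsonlite::write_json(
    report$manifest,
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(report)
}

#' Re-run all statistics with one player excluded
#'
#' Sensitivity analysis for a potential outlier: removes one player's clicks
#' and ratings from the dataset, recomputes the full report, and tabulates
#' the before/after group means of every gated comparison.
#'
#' @param ds A `pc_dataset`.
#' @param team,player Identify the player to exclude.
#' @return A list with `full` and `excluded` reports and a `deltas` tibble.
#' @export
exclude_player_rerun <- function(ds, team, player) {
  keys <- purrr::map_lgl(ds$recordings, function(r) {
    identical(as.integer(r$meta$team), as.integer(team))
  })
  if (!any(keys)) stop("Unknown team: ", team, call. = FALSE)
  if (!player %in% c(1, 2)) stop("Unknown player: ", player, call. = FALSE)
  ds2 <- ds
  ds2$recordings <- lapply(ds$recordings, function(r) {
    if (identical(as.integer(r$meta$team), as.integer(team))) {
      r$clicks <- r$clicks[r$clicks$player != player, ]
    }
    r
  })
  drop <- ds2$truth$team == team & ds2$truth$player == player
  ds2$truth <- ds2$truth[!drop, ]
  qi <- ds2$questionnaires$team == team & ds2$questionnaires$player == player
  ds2$questionnaires$clicked[qi] <- FALSE
  ds2$questionnaires$pas[qi] <- NA_integer_
  ds2$questionnaires$cr[qi] <- NA_integer_
  full <- run_pipeline(ds)
  excluded <- run_pipeline(ds2)
  pick <- function(tbl, suffix) {
    if (nrow(tbl) == 0) {
      return(tibble::tibble(comparison = character()))
    }
    out <- tbl[, c("comparison", "mean1", "mean2", "p_one_tailed")]
    names(out)[-1] <- paste0(c("mean1_", "mean2_", "p_"), suffix)
    out
  }
  deltas <- dplyr::full_join(
    pick(full$gated_tests$table, "full"),
    pick(excluded$gated_tests$table, "excl"),
    by = "comparison"
  )
  list(full = full, excluded = excluded, deltas = deltas,
    player = list(team = team, player = player))
}

#' Write or read a dataset of trial logs
#'
#' `write_dataset()` writes one TSV trial log per recording (via
#' [write_trial_log()]), the questionnaires as `questionnaires.csv`, the
#' ground-truth table as `truth.csv`, and the configuration as
#' `config.yaml`. `read_dataset()` reads such a directory back.
#'
#' @param ds A `pc_dataset`.
#' @param dir Directory.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()` a
#'   `pc_dataset`.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in ds$recordings) {
    fn <- sprintf("trial_T%03d_%02d.tsv", rec$meta$team, rec$meta$trial)
    write_trial_log(rec, file.path(dir, fn))
  }
  readr::write_csv(ds$questionnaires, file.path(dir, "questionnaires.csv"))
  readr::write_csv(ds$truth, file.path(dir, "truth.csv"))
  write_env_config(ds$cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  logs <- sort(list.files(dir, pattern = "^trial_.*\\.tsv$", full.names = TRUE))
  if (length(logs) == 0) stop("No trial logs found in ", dir, call. = FALSE)
  recordings <- lapply(logs, read_trial_log)
  teams <- vapply(recordings, function(r) as.integer(r$meta$team), integer(1))
  trials <- vapply(recordings, function(r) as.integer(r$meta$trial), integer(1))
  qpath <- file.path(dir, "questionnaires.csv")
  questionnaires <- if (file.exists(qpath)) {
    readr::read_csv(qpath, show_col_types = FALSE)
  } else {
    tibble::tibble(
      team = integer(), trial = integer(), player = integer(),
      clicked = logical(), pas = integer(), cr = integer(),
      free_text = character()
    )
  }
  tpath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(tpath)) {
    readr::read_csv(tpath, show_col_types = FALSE)
  } else {
    tibble::tibble(
      team = integer(), trial = integer(), player = integer(),
      scenario = character(), click_step = integer(),
      click_time_ms = numeric(), true_target = character()
    )
  }
  structure(
    list(
      cfg = recordings[[1]]$cfg,
      recordings = recordings,
      truth = truth,
      questionnaires = questionnaires,
      scenario = recordings[[1]]$meta$scenario %||% "unknown",
      n_teams = max(teams),
      n_trials = max(trials),
      seed = recordings[[1]]$meta$seed %||% NA_integer_
    ),
    class = "pc_dataset"
  )
}
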