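#' The 18-step contact-segmentation worked example
#'
#' A small fictitious stimulation series, shipped with the package, that
#' illustrates the contact-segmentation rule: three maximal runs of tactile
#' stimulation, the first two each involving the other's avatar and the
#' player's static object (the static object re-entering within a run is
#' still counted once), the third involving only the other's shadow. The
#' per-type contact counts are avatar = 2, static = 2, shadow = 1.
#'
#' @return `contact_example()`: a list with `stim` (logical vector of length
#'   18) and `overlaps` (tibble with logical columns `avatar`, `shadow`,
#'   `static`). `contact_example_contacts()`: the corresponding
#'   [segment_contacts()] output.
#' @examples
#' count_contacts_by_type(contact_example_contacts())
#' @export
contact_example <- function() {
  path <- system.file("extdata", "contact_worked_example.txt",
    package = "pcrossing", mustWork = TRUE
  )
  lines <- readLines(path)
  parse_row <- function(prefix) {
    ln <- lines[startsWith(lines, prefix)]
    digits <- gsub("[^01]", "", sub(prefix, "", ln))
    as.integer(strsplit(digits, "")[[1]]) == 1L
  }
  list(
    stim = parse_row("stim"),
    overlaps = tibble::tibble(
      avatar = parse_row("avatar"),
      shadow = parse_row("shadow"),
      static = parse_row("static")
    )
  )
}

#' @rdname contact_example
#' @export
contact_example_contacts <- function() {
  ex <- contact_example()
  segment_contacts(ex$stim, ex$overlaps)
}

#' Published tournament results table
#'
#' The per-team results of the original 17-team tournament as printed in the
#' source study: each team's score and, for each of the two players, the
#' number of clicks attributed to the other's avatar, the other's shadow,
#' the player's own static object, and to no identifiable target. These
#' printed aggregates serve as worked-example inputs for the scoring and
#' summary operations.
#'
#' @return `tournament_table()`: one row per team (`team`, `score`, and the
#'   eight per-player click-count columns). `tournament_players()`: the same
#'   data with one row per player (`team`, `player`, `avatar`, `shadow`,
#'   `static`, `none`, `n_clicks`, `accuracy`).
#' @examples
#' tt <- tournament_table()
#' sum(tt$p1_avatar + tt$p2_avatar) # total correct clicks
#' @export
tournament_table <- function() {
  path <- system.file("extdata", "tournament_results.csv",
    package = "pcrossing", mustWork = TRUE
  )
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  tbl$team <- seq_len(nrow(tbl))
  dplyr::relocate(tbl, "team")
}

#' @rdname tournament_table
#' @export
tournament_players <- function() {
  tbl <- tournament_table()
  long <- purrr::map_dfr(1:2, function(p) {
    pre <- paste0("p", p, "_")
    tibble::tibble(
      team = tbl$team,
      player = p,
      avatar = tbl[[paste0(pre, "avatar")]],
      shadow = tbl[[paste0(pre, "shadow")]],
      static = tbl[[paste0(pre, "static")]],
      none = tbl[[paste0(pre, "none")]]
    )
  })
  long$n_clicks <- long$avatar + long$shadow + long$static + long$none
  long$accuracy <- ifelse(long$n_clicks > 0,
    100 * long$avatar / long$n_clicks, NA_real_
  )
  dplyr::arrange(long, .data$team, .data$player)
}
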