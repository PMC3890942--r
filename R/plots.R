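#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trial recording
#'
#' Draws both avatars' trajectories over time, their shadows (dotted) and
#' each player's static object (dashed horizontal lines), with click times
#' marked. Wrap-around jumps are left as-is, matching the circular space.
#'
#' @param object A `trial_recording`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trial_recording
#' @export
autoplot.trial_recording <- function(object, ...) {
  st <- object$steps
  traj <- dplyr::bind_rows(
    tibble::tibble(
      t = st$time_ms / 1000, pos = st$pos1,
      what = "avatar 1", kind = "avatar"
    ),
    tibble::tibble(
      t = st$time_ms / 1000, pos = st$pos2,
      what = "avatar 2", kind = "avatar"
    ),
    tibble::tibble(
      t = st$time_ms / 1000, pos = shadow_positions(object, 1),
      what = "shadow 1", kind = "shadow"
    ),
    tibble::tibble(
      t = st$time_ms / 1000, pos = shadow_positions(object, 2),
      what = "shadow 2", kind = "shadow"
    )
  )
  p <- ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$t, y = .data$pos,
    colour = .data$what, linetype = .data$kind
  )) +
    ggplot2::geom_point(size = 0.2) +
    ggplot2::geom_hline(
      yintercept = object$static_pos, linetype = "dashed",
      colour = "grey50"
    ) +
    ggplot2::scale_linetype_manual(
      values = c(avatar = "solid", shadow = "dotted"), guide = "none"
    ) +
    ggplot2::labs(
      x = "time (s)", y = "position (units)", colour = NULL,
      title = "Trial trajectories"
    )
  if (nrow(object$clicks) > 0) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$clicks$time_ms / 1000,
      linetype = "dotdash", colour = "black"
    )
  }
  p
}

#' Plot a synchrony analysis
#'
#' Side-by-side relative-frequency histograms of the pairwise (within-trial)
#' and randomized (cross-trial) inter-click delay distributions.
#'
#' @param object A `synchrony_delays` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot synchrony_delays
#' @export
autoplot.synchrony_delays <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$bin_lo + object$bin_width / 2, y = .data$freq,
    fill = .data$kind
  )) +
    ggplot2::geom_col(position = "dodge", width = object$bin_width * 0.9) +
    ggplot2::labs(
      x = "delay between clicks (s)", y = "relative frequency",
      fill = NULL, title = "Inter-click delays: pairwise vs randomized"
    )
}

#' Plot a rating frequency table
#'
#' Bar chart of the relative frequency of each rating level within the
#' Joint Success / Single Success / Wrong Click categories.
#'
#' @param tbl Output of [rating_frequency_table()].
#' @param scale_name Axis label (e.g. "PAS" or "CR").
#' @return A ggplot.
#' @export
plot_rating_frequencies <- function(tbl, scale_name = "rating") {
  ggplot2::ggplot(tbl, ggplot2::aes(
    x = factor(.data$level), y = .data$freq, fill = .data$category
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = paste(scale_name, "level"), y = "relative frequency", fill = NULL
    )
}
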