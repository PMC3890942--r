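#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a gated test result
#'
#' @param x A `gated_test` from [gated_comparison()].
#' @param ... Unused.
#' @return A one-row tibble with the group summaries, the variance gate
#'   (`f_statistic`, `f_p`, `chosen_test`) and the one-tailed t-test
#'   (`t_statistic`, `df`, `p_one_tailed`).
#' @method tidy gated_test
#' @export
tidy.gated_test <- function(x, ...) {
  tibble::tibble(
    group1 = x$labels[1], group2 = x$labels[2],
    mean1 = x$mean_x, mean2 = x$mean_y,
    n1 = x$n_x, n2 = x$n_y,
    f_statistic = x$f_statistic, f_p = x$f_p,
    chosen_test = x$chosen_test,
    t_statistic = x$t_statistic, df = x$df,
    p_one_tailed = x$p_one_tailed,
    direction = x$labels[if (x$direction == "x") 1 else 2]
  )
}

#' @rdname tidy.gated_test
#' @method glance gated_test
#' @export
glance.gated_test <- function(x, ...) {
  tibble::tibble(
    chosen_test = x$chosen_test,
    t_statistic = x$t_statistic,
    df = x$df,
    p_one_tailed = x$p_one_tailed
  )
}

#' Tidy a turn-taking score
#'
#' @param x A `tt_score`.
#' @param ... Unused.
#' @return A one-row tibble with `tt`, `c1`, `c2`, `t_steps`.
#' @method tidy tt_score
#' @export
tidy.tt_score <- function(x, ...) {
  tibble::tibble(tt = x$tt, c1 = x$c1, c2 = x$c2, t_steps = x$t_steps)
}

#' Tidy a synchrony analysis
#'
#' @param x A `synchrony_delays` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble with one row per bin and kind
#'   (`pairwise` / `randomized`). `glance()`: a one-row tibble with the
#'   fractions of delays shorter than 10 s.
#' @method tidy synchrony_delays
#' @export
tidy.synchrony_delays <- function(x, ...) {
  tidyr::pivot_longer(
    x$histogram,
    cols = c("freq_pairwise", "freq_randomized"),
    names_to = "kind", names_prefix = "freq_", values_to = "freq"
  )
}

#' @rdname tidy.synchrony_delays
#' @method glance synchrony_delays
#' @export
glance.synchrony_delays <- function(x, ...) {
  tibble::tibble(
    n_trials = length(x$pairwise),
    n_randomized_pairs = length(x$randomized),
    short_pairwise = short_delay_fraction(x$pairwise),
    short_randomized = short_delay_fraction(x$randomized)
  )
}
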