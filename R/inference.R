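#' F-test for equality of variances
#'
#' Compares two sample variances with the larger variance in the numerator,
#' so the reported F statistic is at least 1, with a two-sided p-value from
#' the F distribution. Used as the gate that decides between the pooled
#' (Student) and unequal-variance (Welch) two-sample t-test.
#'
#' @param x,y Numeric samples (each of size at least 2).
#' @param alpha Gate level: variances are treated as equal when the
#'   two-sided p-value is at least `alpha`.
#' @return A list with `f_statistic`, `f_p`, `df` (numerator, denominator)
#'   and `equal` (logical).
#' @examples
#' f_test_equal_variance(rnorm(10), rnorm(10, sd = 2))
#' @export
f_test_equal_variance <- function(x, y, alpha = 0.05) {
  if (length(x) < 2 || length(y) < 2) {
    stop("Each sample needs at least 2 observations.", call. = FALSE)
  }
  v <- c(stats::var(x), stats::var(y))
  if (all(v == 0)) {
    stop("Degenerate input: both samples have zero variance.", call. = FALSE)
  }
  big_first <- v[1] >= v[2]
  a <- if (big_first) x else y
  b <- if (big_first) y else x
  if (stats::var(b) == 0) {
    return(list(
      f_statistic = Inf, f_p = 0,
      df = c(length(a) - 1L, length(b) - 1L), equal = FALSE
    ))
  }
  vt <- stats::var.test(a, b)
  p <- vt$p.value
  list(
    f_statistic = unname(vt$statistic),
    f_p = p,
    df = unname(vt$parameter),
    equal = p >= alpha
  )
}

#' One-tailed two-sample t-test
#'
#' Either the pooled-variance (Student) test with `n1 + n2 - 2` degrees of
#' freedom or the unequal-variance (Welch) test with Welch-Satterthwaite
#' degrees of freedom, with a one-tailed p-value in an explicitly stated
#' direction. The direction is never inferred from the data.
#'
#' @param x,y Numeric samples.
#' @param equal_var Use the pooled test (`TRUE`) or Welch (`FALSE`).
#' @param direction `"x"` or `"y"`: which sample's mean is hypothesized to
#'   be larger under the alternative.
#' @return A list with `t_statistic` (sign of `mean(x) - mean(y)`), `df`,
#'   `p_one_tailed`, group means and sizes, and `method`.
#' @examples
#' one_tailed_two_sample_t(c(2, 3, 4), c(1, 2, 3), TRUE, direction = "x")
#' @export
one_tailed_two_sample_t <- function(x, y, equal_var, direction = c("x", "y")) {
  direction <- match.arg(direction)
  if (length(x) < 2 || length(y) < 2) {
    stop("Each sample needs at least 2 observations.", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("Degenerate input: both samples have zero variance.", call. = FALSE)
  }
  alternative <- if (direction == "x") "greater" else "less"
  tt <- stats::t.test(x, y,
    var.equal = equal_var, alternative = alternative, mu = 0
  )
  list(
    t_statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_one_tailed = tt$p.value,
    mean_x = mean(x), mean_y = mean(y),
    n_x = length(x), n_y = length(y),
    method = if (equal_var) "student" else "welch"
  )
}

#' Variance-gated one-tailed comparison of two groups
#'
#' The statistical procedure used throughout the analysis: the equality of
#' the two group variances is first checked with an F-test at level `alpha`;
#' if the F-test does not reject, the groups are compared with a one-tailed
#' pooled-variance (Student) t-test, otherwise with a one-tailed
#' unequal-variance (Welch) t-test. The hypothesized direction must be given
#' explicitly.
#'
#' @inheritParams one_tailed_two_sample_t
#' @param alpha Level of the variance gate.
#' @param labels Length-2 character: names of the two groups, used in
#'   printing and in [generics::tidy()] output.
#' @return A `gated_test` object.
#' @examples
#' g <- gated_comparison(rnorm(20, 1), rnorm(20), direction = "x",
#'   labels = c("treated", "control"))
#' tidy(g)
#' @export
gated_comparison <- function(x, y, alpha = 0.05, direction = c("x", "y"),
                             labels = c("x", "y")) {
  direction <- match.arg(direction)
  ft <- f_test_equal_variance(x, y, alpha = alpha)
  tt <- one_tailed_two_sample_t(x, y,
    equal_var = ft$equal, direction = direction
  )
  structure(
    c(
      list(
        f_statistic = ft$f_statistic, f_p = ft$f_p,
        chosen_test = tt$method, alpha = alpha,
        direction = direction, labels = labels
      ),
      tt[c(
        "t_statistic", "df", "p_one_tailed", "mean_x", "mean_y",
        "n_x", "n_y"
      )]
    ),
    class = "gated_test"
  )
}

#' @export
print.gated_test <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<gated_test: %s vs %s>\n",
      "  F = %.3f (p = %.4g) -> %s t-test\n",
      "  means: %s = %.4g (n = %d), %s = %.4g (n = %d)\n",
      "  one-tailed (%s larger): t = %.3f, df = %.2f, p = %.4g\n"
    ),
    x$labels[1], x$labels[2], x$f_statistic, x$f_p,
    if (x$chosen_test == "student") "pooled (Student)" else "Welch",
    x$labels[1], x$mean_x, x$n_x, x$labels[2], x$mean_y, x$n_y,
    x$labels[if (x$direction == "x") 1 else 2],
    x$t_statistic, x$df, x$p_one_tailed
  ))
  invisible(x)
}

#' Click-synchrony randomization analysis
#'
#' Within jointly successful trials, the two players' click times tend to be
#' close even though neither can sense the other's click. The pairwise
#' distribution collects the absolute delay between the two clicks *within*
#' each trial; the randomized null collects the delays between clicks from
#' *different* trials (every cross-trial pairing of player 1's click with
#' player 2's click, enumerated deterministically). Both are binned on a
#' common grid and normalized to relative frequencies. An excess of short
#' pairwise delays relative to the randomized distribution indicates that
#' synchrony is an interactive achievement rather than entrainment to a
#' shared external time frame.
#'
#' @param joint_clicks Tibble with one row per Joint Success trial and
#'   numeric columns `t1`, `t2`: the two players' click times in seconds
#'   (see [joint_click_times()]).
#' @param bin_width Histogram bin width in seconds.
#' @param seed Optional seed used only if `max_pairs` subsampling applies.
#' @param max_pairs Optional cap on the number of cross-trial pairs; beyond
#'   it pairs are subsampled (seeded). Default keeps full enumeration.
#' @return A `synchrony_delays` object: list with numeric `pairwise` and
#'   `randomized` delay vectors and a `histogram` tibble (`bin_lo`,
#'   `bin_hi`, `freq_pairwise`, `freq_randomized`).
#' @export
synchrony_analysis <- function(joint_clicks, bin_width = 2, seed = NULL,
                               max_pairs = Inf) {
  stopifnot(all(c("t1", "t2") %in% names(joint_clicks)))
  n <- nrow(joint_clicks)
  if (n < 2) {
    stop("Need at least 2 jointly successful trials for the randomized null.",
      call. = FALSE
    )
  }
  t1 <- joint_clicks$t1
  t2 <- joint_clicks$t2
  pairwise <- abs(t1 - t2)
  cross <- expand.grid(i = seq_len(n), j = seq_len(n))
  cross <- cross[cross$i != cross$j, ]
  randomized <- abs(t1[cross$i] - t2[cross$j])
  if (is.finite(max_pairs) && length(randomized) > max_pairs) {
    pick <- if (is.null(seed)) {
      seq_len(max_pairs)
    } else {
      with_local_seed(seed, sample.int(length(randomized), max_pairs))
    }
    randomized <- randomized[pick]
  }
  hi <- max(pairwise, randomized, bin_width)
  edges <- seq(0, ceiling(hi / bin_width) * bin_width, by = bin_width)
  binfreq <- function(d) {
    cnt <- graphics::hist(d, breaks = edges, plot = FALSE, right = FALSE)$counts
    cnt / sum(cnt)
  }
  structure(
    list(
      pairwise = pairwise,
      randomized = randomized,
      bin_width = bin_width,
      histogram = tibble::tibble(
        bin_lo = edges[-length(edges)],
        bin_hi = edges[-1],
        freq_pairwise = binfreq(pairwise),
        freq_randomized = binfreq(randomized)
      )
    ),
    class = "synchrony_delays"
  )
}

#' @export
print.synchrony_delays <- function(x, ...) {
  cat(sprintf(
    "<synchrony_delays: %d trials, %d randomized pairs, bin width %g s>\n",
    length(x$pairwise), length(x$randomized), x$bin_width
  ))
  cat(sprintf(
    "  fraction of delays < 10 s: pairwise %.3f, randomized %.3f\n",
    short_delay_fraction(x$pairwise), short_delay_fraction(x$randomized)
  ))
  invisible(x)
}

#' @rdname synchrony_analysis
#' @param delays Numeric vector of delays in seconds.
#' @param cutoff Cutoff in seconds.
#' @return `short_delay_fraction()`: the fraction of delays strictly below
#'   `cutoff`.
#' @export
short_delay_fraction <- function(delays, cutoff = 10) {
  mean(delays < cutoff)
}

#' Click-time pairs of jointly successful trials
#'
#' @param click_tbl Attributed click table (see [attribute_clicks()]) with
#'   `click_category` added by [classify_clicks()], or raw with `target`.
#' @return A tibble with columns `team`, `trial`, `t1`, `t2` (seconds), one
#'   row per Joint Success trial.
#' @export
joint_click_times <- function(click_tbl) {
  if (!"click_category" %in% names(click_tbl)) {
    click_tbl <- classify_clicks(click_tbl)
  }
  js <- click_tbl[click_tbl$click_category == "joint_success", ]
  wide <- tidyr::pivot_wider(
    js[, c("team", "trial", "player", "click_time_ms")],
    names_from = "player", values_from = "click_time_ms",
    names_prefix = "t"
  )
  wide$t1 <- wide$t1 / 1000
  wide$t2 <- wide$t2 / 1000
  wide
}
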