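test_that("the variance F-test reports larger/smaller ratio with two-sided p", {
  x <- rep(c(1, 2), 10)
  expect_equal(f_test_equal_variance(x, x)$f_statistic, 1)
  # variances 4 and 1 at n = 10 each: F = 4, p from F(9, 9)
  a <- c(1, 3, 5, 7, 9, 1, 3, 5, 7, 9) # var = 8.888...
  b <- a / 2 # var ratio exactly 4
  ft <- f_test_equal_variance(a, b)
  expect_equal(ft$f_statistic, 4)
  expect_equal(ft$f_p, 2 * pf(4, 9, 9, lower.tail = FALSE))
  # argument order must not matter for the gate
  ft2 <- f_test_equal_variance(b, a)
  expect_equal(ft2$f_statistic, 4)
  expect_equal(ft2$f_p, ft$f_p)
  # cross-check against stats::var.test with the larger variance first
  vt <- var.test(a, b)
  expect_equal(ft$f_statistic, unname(vt$statistic))
  expect_equal(ft$f_p, vt$p.value)
  # degenerate cases
  expect_false(f_test_equal_variance(rep(1, 5), rnorm(5))$equal)
  expect_error(f_test_equal_variance(rep(1, 5), rep(2, 5)), "zero variance")
})

test_that("one-tailed t-tests match hand computations", {
  x <- c(1, 2, 3)
  # identical groups: t = 0, p = 0.5
  r0 <- one_tailed_two_sample_t(x, x + 0, equal_var = TRUE, direction = "x")
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_one_tailed, 0.5)
  # textbook pooled case, direction y > x
  y <- c(2, 3, 4)
  r <- one_tailed_two_sample_t(x, y, equal_var = TRUE, direction = "y")
  oracle <- oracle_pooled_t(x, y, larger = "y")
  expect_equal(r$t_statistic, oracle$t)
  expect_equal(r$df, oracle$df)
  expect_equal(r$p_one_tailed, oracle$p)
  expect_equal(r$method, "student")
  # Welch agrees with Student when variances and sizes are equal
  set.seed(2)
  g1 <- rnorm(12)
  g2 <- 2 + (g1 - mean(g1)) * 1 + mean(g1) # same spread
  rs <- one_tailed_two_sample_t(g1, g2, TRUE, "y")
  rw <- one_tailed_two_sample_t(g1, g2, FALSE, "y")
  expect_equal(rw$t_statistic, rs$t_statistic)
  expect_equal(rw$p_one_tailed, rs$p_one_tailed, tolerance = 1e-12)
  expect_error(
    one_tailed_two_sample_t(rep(1, 4), rep(2, 4), TRUE, "x"),
    "zero variance"
  )
})

test_that("gated_comparison picks Student or Welch via the F gate", {
  set.seed(5)
  x <- rnorm(30)
  y <- rnorm(30)
  g <- gated_comparison(x, y, direction = "x")
  expect_equal(g$chosen_test, "student")
  yw <- rnorm(30, sd = 4) # variance ratio 16: the gate must reject
  gw <- gated_comparison(x, yw, direction = "x")
  expect_equal(gw$chosen_test, "welch")
  td <- tidy(gw)
  expect_equal(td$chosen_test, "welch")
  expect_equal(td$mean1, mean(x))
  expect_equal(glance(gw)$p_one_tailed, gw$p_one_tailed)
})

test_that("power of the gated test grows with sample size", {
  # PAS-like groups separated by 0.4 sd: average one-tailed p drops with n
  set.seed(6)
  mean_p <- vapply(c(10, 60), function(n) {
    mean(vapply(1:150, function(i) {
      gated_comparison(rnorm(n, 0.4), rnorm(n), direction = "x")$p_one_tailed
    }, numeric(1)))
  }, numeric(1))
  expect_lt(mean_p[2], mean_p[1])
})

test_that("type-I error of the gated one-tailed test is near nominal", {
  set.seed(7)
  n <- 12
  rejections <- 0L
  reps <- 10000L
  for (i in seq_len(reps)) {
    p <- gated_comparison(rnorm(n), rnorm(n), direction = "x")$p_one_tailed
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_lt(abs(rejections / reps - 0.05), 0.01)
})

test_that("synchrony analysis enumerates cross-trial pairings exactly", {
  # simultaneous clicks: pairwise delays all zero
  sim <- tibble::tibble(t1 = c(10, 20, 30), t2 = c(10, 20, 30))
  sy <- synchrony_analysis(sim)
  expect_equal(sy$pairwise, c(0, 0, 0))
  expect_equal(sum(sy$histogram$freq_pairwise), 1)
  expect_equal(sum(sy$histogram$freq_randomized), 1)
  # alternating fixed click times: randomized delays by brute force
  alt <- tibble::tibble(t1 = c(10, 20, 10, 20), t2 = c(10, 20, 10, 20))
  sy2 <- synchrony_analysis(alt)
  brute <- c()
  for (i in 1:4) {
    for (j in 1:4) {
      if (i != j) brute <- c(brute, abs(alt$t1[i] - alt$t2[j]))
    }
  }
  expect_equal(sort(sy2$randomized), sort(brute))
  expect_equal(sy2$pairwise, rep(0, 4))
  # randomized distribution is invariant under permuting trials
  set.seed(8)
  jc <- tibble::tibble(t1 = runif(8, 5, 55), t2 = runif(8, 5, 55))
  perm <- jc[sample(8), ]
  expect_equal(
    sort(synchrony_analysis(jc)$randomized),
    sort(synchrony_analysis(perm)$randomized)
  )
  expect_error(synchrony_analysis(tibble::tibble(t1 = 1, t2 = 2)), "at least 2")
})

test_that("short delays dominate pairwise for interacting pairs", {
  ds <- generate_dataset(3, 8, scenario = "turn_takers", seed = 17)
  cl <- classify_clicks(attribute_clicks(ds))
  sy <- synchrony_analysis(joint_click_times(cl))
  expect_gt(
    short_delay_fraction(sy$pairwise),
    short_delay_fraction(sy$randomized)
  )
  g <- glance(sy)
  expect_equal(g$n_trials, length(sy$pairwise))
})

test_that("excluding a player recomputes statistics consistently", {
  ds <- generate_dataset(4, 5, scenario = "mixed", seed = 41)
  # excluding a player with no clicks changes nothing
  clicked <- unique(ds$truth[, c("team", "player")])
  all_players <- tidyr::expand_grid(team = 1:4, player = 1:2)
  silent <- dplyr::anti_join(all_players, clicked, by = c("team", "player"))
  rerun_target <- if (nrow(silent) > 0) silent[1, ] else NULL
  if (!is.null(rerun_target)) {
    out <- exclude_player_rerun(ds, rerun_target$team, rerun_target$player)
    expect_equal(out$full$gated_tests$table, out$excluded$gated_tests$table)
  }
  # excluding a clicking player removes their rows everywhere
  tgt <- clicked[1, ]
  out2 <- exclude_player_rerun(ds, tgt$team, tgt$player)
  ex_clicks <- out2$excluded$clicks
  expect_false(any(ex_clicks$team == tgt$team & ex_clicks$player == tgt$player))
  expect_true(all(c("mean1_full", "mean1_excl") %in% names(out2$deltas)))
  expect_error(exclude_player_rerun(ds, 99, 1), "Unknown team")
  expect_error(exclude_player_rerun(ds, 1, 3), "Unknown player")
})

test_that("excluding the sole low-awareness reporter empties that rating level", {
  ds <- generate_dataset(2, 6, scenario = "turn_takers", seed = 53)
  # force one player to mimic the outlier pattern: correct clicks, PAS 1
  qi <- ds$questionnaires$team == 1 & ds$questionnaires$player == 1 &
    ds$questionnaires$clicked
  ds$questionnaires$pas[qi] <- 1L
  cl <- classify_clicks(attribute_clicks(ds))
  before <- rating_frequency_table(ds$questionnaires, cl, "pas")
  expect_gt(before$n[before$category == "JointSuccess" & before$level == 1], 0)
  out <- exclude_player_rerun(ds, 1, 1)
  after <- out$excluded$pas_table
  expect_equal(after$n[after$category == "JointSuccess" & after$level == 1], 0)
  # group means move up once the low reports are gone
  cmp <- out$deltas[out$deltas$comparison == "pas_joint_vs_wrong", ]
  if (nrow(cmp) == 1 && !is.na(cmp$mean1_full)) {
    expect_gte(cmp$mean1_excl, cmp$mean1_full)
  }
})
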