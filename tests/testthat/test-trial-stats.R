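test_that("trial classification follows the joint/single/wrong definitions", {
  expect_equal(classify_trial(c("avatar", "avatar")), "JointSuccess")
  expect_equal(classify_trial(c("avatar", "shadow")), "SingleSuccess")
  expect_equal(classify_trial("avatar"), "SingleSuccess")
  expect_equal(classify_trial(c("shadow", "none")), "WrongOnly")
  expect_equal(classify_trial(character(0)), "NoClicks")
  expect_error(classify_trial(c("avatar", "avatar", "shadow")), "one retained click")
})

test_that("classify_clicks and classify_trials agree with each other", {
  clicks <- tibble::tibble(
    team = c(1, 1, 1, 1, 2, 2),
    trial = c(1, 1, 2, 3, 1, 2),
    player = c(1, 2, 1, 2, 1, 1),
    target = c("avatar", "avatar", "avatar", "none", "shadow", "avatar")
  )
  cc <- classify_clicks(clicks)
  expect_equal(
    cc$click_category,
    c(
      "joint_success", "joint_success", "single_success", "wrong",
      "wrong", "single_success"
    )
  )
  all_trials <- tidyr::expand_grid(team = 1:2, trial = 1:3)
  tr <- classify_trials(clicks, all_trials)
  expect_equal(nrow(tr), 6)
  got <- tr$outcome[order(tr$team, tr$trial)]
  expect_equal(got, c(
    "JointSuccess", "SingleSuccess", "WrongOnly",
    "WrongOnly", "SingleSuccess", "NoClicks"
  ))
  # bookkeeping identity: 2 x joint trials + singles + wrongs = all clicks
  expect_equal(
    2 * sum(tr$outcome == "JointSuccess") +
      sum(cc$click_category == "single_success") +
      sum(cc$click_category == "wrong"),
    nrow(clicks)
  )
})

test_that("team scoring adds correct clicks and subtracts wrong ones", {
  expect_equal(team_score(rep("avatar", 30)), 30L)
  expect_equal(team_score(rep("avatar", 27)), 27L)
  expect_equal(
    team_score(c(rep("avatar", 12), rep("shadow", 8), rep("static", 5))),
    -1L
  )
  # clicks with no identifiable target count as wrong
  expect_equal(team_score(c("avatar", "none")), 0L)
  expect_equal(team_score(character(0)), 0L)
})

test_that("every printed tournament score is reproduced from its click counts", {
  tt <- tournament_table()
  expect_equal(nrow(tt), 17)
  recomputed <- with(
    tt,
    (p1_avatar - p1_shadow - p1_static - p1_none) +
      (p2_avatar - p2_shadow - p2_static - p2_none)
  )
  expect_equal(recomputed, tt$score)
  # the same rule through team_score() on expanded click vectors
  for (i in seq_len(nrow(tt))) {
    targets <- c(
      rep("avatar", tt$p1_avatar[i] + tt$p2_avatar[i]),
      rep("shadow", tt$p1_shadow[i] + tt$p2_shadow[i]),
      rep("static", tt$p1_static[i] + tt$p2_static[i]),
      rep("none", tt$p1_none[i] + tt$p2_none[i])
    )
    expect_equal(team_score(targets), tt$score[i])
  }
})

test_that("clicking accuracy is a percentage and undefined without clicks", {
  expect_equal(clicking_accuracy(c(rep("avatar", 12), "shadow")), 1200 / 13)
  expect_equal(round(clicking_accuracy(c(rep("avatar", 12), "shadow"))), 92)
  expect_equal(clicking_accuracy(rep("avatar", 15)), 100)
  expect_equal(clicking_accuracy(rep("shadow", 5)), 0)
  expect_true(is.na(clicking_accuracy(character(0))))
  tbl <- clicking_accuracies(tibble::tibble(
    team = c(1, 1, 1), player = c(1, 1, 2),
    target = c("avatar", "avatar", "shadow")
  ))
  expect_equal(tbl$accuracy, c(100, 0))
})

test_that("per-contact click probabilities divide clicks by contacts", {
  out <- click_probability_per_contact(
    c(avatar = 338, shadow = 33, static = 11),
    c(avatar = 28996, shadow = 5046, static = 5621)
  )
  expect_equal(round(out$probability, 2), c(1.17, 0.65, 0.20))
  zero <- click_probability_per_contact(
    c(avatar = 0), c(avatar = 100)
  )
  expect_equal(zero$probability, 0)
  expect_error(
    click_probability_per_contact(c(avatar = 3), c(avatar = 0)),
    "zero contacts"
  )
})

test_that("rating tables normalize within category and flag empties", {
  q <- tibble::tibble(
    team = c(1, 1, 1, 2), trial = c(1, 1, 2, 1), player = c(1, 2, 1, 1),
    pas = c(4L, 4L, 3L, NA)
  )
  cl <- tibble::tibble(
    team = c(1, 1, 1, 2), trial = c(1, 1, 2, 1), player = c(1, 2, 1, 1),
    target = c("avatar", "avatar", "avatar", "avatar"),
    click_category = c(
      "joint_success", "joint_success", "joint_success", "single_success"
    )
  )
  tbl <- rating_frequency_table(q, cl, "pas")
  joint <- tbl[tbl$category == "JointSuccess", ]
  expect_equal(joint$freq, c(0, 0, 1 / 3, 2 / 3))
  expect_equal(sum(joint$freq), 1, tolerance = 1e-12)
  single <- tbl[tbl$category == "SingleSuccess", ]
  expect_true(all(single$empty))
  expect_equal(single$n_missing[1], 1)
  wrong <- tbl[tbl$category == "WrongClick", ]
  expect_true(all(wrong$empty))
  # a rating without any matching click warns
  q2 <- dplyr::bind_rows(
    q, tibble::tibble(team = 9, trial = 9, player = 1, pas = 2L)
  )
  expect_warning(rating_frequency_table(q2, cl, "pas"), "without a matching click")
})

test_that("rating frequencies sum to one on generated data", {
  ds <- generate_dataset(3, 5, scenario = "mixed", seed = 31)
  cl <- classify_clicks(attribute_clicks(ds))
  for (scale in c("pas", "cr")) {
    tbl <- rating_frequency_table(ds$questionnaires, cl, scale)
    sums <- tapply(tbl$freq, tbl$category, sum)
    for (cat in names(sums)) {
      if (!all(tbl$empty[tbl$category == cat])) {
        expect_equal(unname(sums[cat]), 1, tolerance = 1e-12)
      }
    }
  }
})
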