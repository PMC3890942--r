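cfg <- env_config()

test_that("stationary non-overlapping pair never gets stimulated", {
  rec <- simulate_trial(
    list(make_stationary_agent(), make_stationary_agent()),
    cfg,
    starts = c(0, 300), static_pos = c(100, 500)
  )
  expect_equal(nrow(rec$steps), 6000)
  expect_false(any(rec$steps$stim1))
  expect_false(any(rec$steps$stim2))
  expect_equal(nrow(rec$clicks), 0)
  expect_equal(nrow(contacts(rec, 1)), 0)
})

test_that("a full-circle sweep is stimulated exactly at hand-computed steps", {
  # A starts at 0 and moves +1 unit/step; B holds at 300 (shadow at 450),
  # A's static sits at 100. Strict overlap (<4) puts contact with an object
  # at position q exactly at the steps t with |t - q| <= 3.
  rec <- simulate_trial(
    list(
      make_scanner_agent(speed = 1, span = 600, click_window = c(Inf, Inf)),
      make_stationary_agent()
    ),
    cfg,
    starts = c(0, 300), static_pos = c(100, 520)
  )
  first600 <- rec$steps$stim1[1:601] # steps 0..600 (outbound sweep)
  expected_steps <- sort(c(97:103, 297:303, 447:453))
  expect_equal(which(first600) - 1L, expected_steps)
  # B feels A's shadow (at A + 150) sweeping past and A's avatar (mutual),
  # but nothing when A touches B's own shadow at 450
  bsteps <- which(rec$steps$stim2[1:601]) - 1L
  expect_equal(bsteps, sort(c(147:153, 297:303)))
})

test_that("shadow contact stimulates only the toucher", {
  # A parks right on B's shadow (B at 300, shadow at 450)
  rec <- simulate_trial(
    list(make_stationary_agent(), make_stationary_agent()),
    cfg,
    starts = c(450, 300), static_pos = c(100, 520)
  )
  expect_true(all(rec$steps$stim1))
  expect_false(any(rec$steps$stim2))
  ov <- overlap_channels(rec, 1)
  expect_true(all(ov$shadow))
  expect_false(any(ov$avatar | ov$static))
})

test_that("recording invariants hold on simulated trials", {
  for (seed in 1:3) {
    rec <- simulate_trial(
      list(
        make_scanner_agent(speed = 0.8, span = 300, seed = seed),
        make_scanner_agent(speed = 0.6, span = 450, seed = seed + 100)
      ),
      cfg,
      seed = seed
    )
    expect_true(all(rec$steps$pos1 >= 0 & rec$steps$pos1 < 600))
    expect_true(all(rec$steps$pos2 >= 0 & rec$steps$pos2 < 600))
    ov1 <- overlap_channels(rec, 1)
    ov2 <- overlap_channels(rec, 2)
    # stim is the OR of the three channels
    expect_equal(rec$steps$stim1, ov1$avatar | ov1$shadow | ov1$static)
    expect_equal(rec$steps$stim2, ov2$avatar | ov2$shadow | ov2$static)
    # mutual avatar contact is symmetric
    expect_equal(ov1$avatar, ov2$avatar)
    # rigid link: shadow moves exactly with its avatar
    sh <- shadow_positions(rec, 1)
    dv_avatar <- signed_displacement(
      rec$steps$pos1[-6000], rec$steps$pos1[-1], 600
    )
    dv_shadow <- signed_displacement(sh[-6000], sh[-1], 600)
    expect_equal(dv_shadow, dv_avatar, tolerance = 1e-12)
  }
})

test_that("simulation errors name the player emitting bad velocity", {
  bad <- structure(
    list(
      init = function() list(),
      move = function(state, t, pos, stim) {
        list(vel = if (t >= 5) NaN else 1, click = FALSE, state = state)
      },
      label = "bad", params = list()
    ),
    class = "agent_controller"
  )
  expect_error(
    simulate_trial(list(bad, make_stationary_agent()), cfg,
      starts = c(0, 300), static_pos = c(100, 500)
    ),
    "player 1 .* step 5"
  )
})

test_that("scanner agent kinematics: span, period, determinism", {
  # speed 1 over the full 600-unit circle: triangle period 1200 steps
  rec <- simulate_trial(
    list(
      make_scanner_agent(speed = 1, span = 600, click_window = c(Inf, Inf)),
      make_stationary_agent()
    ),
    cfg,
    starts = c(0, 300), static_pos = c(100, 520)
  )
  expect_equal(rec$steps$pos1[1201], rec$steps$pos1[1])
  expect_equal(rec$steps$pos1[602], 599) # reversal at the span end
  # same seed -> identical trajectory
  r1 <- simulate_trial(
    list(make_scanner_agent(seed = 5), make_scanner_agent(seed = 6)),
    cfg,
    starts = c(0, 300), static_pos = c(100, 520)
  )
  r2 <- simulate_trial(
    list(make_scanner_agent(seed = 5), make_scanner_agent(seed = 6)),
    cfg,
    starts = c(0, 300), static_pos = c(100, 520)
  )
  expect_identical(r1$steps, r2$steps)
  expect_error(make_scanner_agent(speed = 0), "positive")
})

test_that("paired turn-takers alternate and click; a lone one stays silent", {
  p1 <- make_turn_taker_agent(role = 1, seed = 3, start_delay_steps = 500)
  p2 <- make_turn_taker_agent(role = 2, seed = 4, start_delay_steps = 500)
  rec <- simulate_trial(list(p1, p2), cfg,
    starts = c(100, 102), static_pos = c(200, 480)
  )
  expect_equal(sort(rec$clicks$player), c(1L, 2L))
  for (j in 1:2) {
    s <- tt_before_click(rec, rec$clicks$player[j], rec$clicks$step[j])
    expect_gt(s$tt, 0.8) # near-perfect exchange over the pre-click window
  }
  # windowed over a whole number of exchange cycles the score is exactly 1:
  m1 <- binarize_movement(rec$steps$pos1, cfg)
  m2 <- binarize_movement(rec$steps$pos2, cfg)
  onset <- 500 # contact has been continuous, so engagement starts at the delay
  idx <- (onset + 1):(onset + 1000)
  expect_equal(turn_taking_score(m1[idx], m2[idx])$tt, 1)

  # out of range of everything: never engages, never clicks
  lone <- simulate_trial(
    list(
      make_turn_taker_agent(role = 1, seed = 3),
      make_stationary_agent()
    ),
    cfg,
    starts = c(0, 300), static_pos = c(100, 520)
  )
  expect_false(any(lone$steps$stim1))
  expect_equal(nrow(lone$clicks), 0)
})

test_that("generate_dataset is reproducible and sized correctly", {
  d1 <- generate_dataset(2, 3, scenario = "mixed", seed = 99)
  d2 <- generate_dataset(2, 3, scenario = "mixed", seed = 99)
  expect_equal(length(d1$recordings), 6)
  expect_identical(
    lapply(d1$recordings, `[[`, "steps"),
    lapply(d2$recordings, `[[`, "steps")
  )
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$questionnaires, d2$questionnaires)
  d3 <- generate_dataset(2, 3, scenario = "mixed", seed = 100)
  expect_false(identical(d1$truth, d3$truth))

  still <- generate_dataset(1, 1, scenario = "stationary", seed = 1)
  expect_equal(nrow(still$truth), 0)

  expect_error(generate_dataset(1, 1, scenario = "flying", seed = 1))
})

test_that("synthetic ratings reflect click context", {
  ds <- generate_dataset(4, 6, scenario = "mixed", seed = 21)
  q <- ds$questionnaires
  expect_true(all(q$pas[q$clicked] %in% 1:4))
  expect_true(all(is.na(q$pas[!q$clicked])))
  cl <- classify_clicks(attribute_clicks(ds))
  tbl <- rating_frequency_table(q, cl, "pas")
  joint <- tbl[tbl$category == "JointSuccess", ]
  expect_equal(joint$level[which.max(joint$freq)], 4) # modal level 4
})
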