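test_that("the conflict scheduler hits the target time on the grid", {
  # head-on co-altitude closed form: lateral < 5 when t > (d0 - 5) / (2v)
  sch <- schedule_conflict(100, c("AAA111", "BBB222"),
                           speeds_kn = c(450, 450), crossing_angle_deg = 180,
                           level_alt_ft = 35000, vert_margin_s = 40)
  expect_equal(sch$violation_s, 100)
  v <- 450 / 3600
  wp <- sch$trajectories$AAA111$waypoints
  wp2 <- sch$trajectories$BBB222$waypoints
  d0 <- sqrt((wp$x_nm[1] - wp2$x_nm[1])^2 + (wp$y_nm[1] - wp2$y_nm[1])^2)
  expect_equal(ceiling((d0 - 5) / (2 * v)), 100)

  for (seed in 1:10) {
    set.seed(seed)
    target <- sample(60:400, 1)
    sch <- schedule_conflict(target, c("AAA111", "BBB222"),
                             speeds_kn = runif(2, 380, 480),
                             crossing_angle_deg = runif(1, 25, 155),
                             level_alt_ft = 35000,
                             conflict_point_nm = runif(2, -15, 15))
    expect_lte(abs(sch$violation_s - target), 1)
  }
  expect_error(schedule_conflict(100, c("A", "B"), c(400, 400), 0),
               "non-closing")
})

test_that("scenarios carry the scripted traffic for each condition", {
  sc <- generate_scenario(condition(12, "high"))
  expect_equal(length(sc$aircraft), 12)
  expect_length(sc$conflicts, 2)
  expect_setequal(sc$conflicts$easy$aircraft, c("POB456", "HYG532"))
  expect_setequal(sc$conflicts$difficult$aircraft,
                  c("REV756", "KET456", "GPL751"))
  expect_true("SRT346" %in% names(sc$aircraft))

  sc6 <- generate_scenario(condition(6, "low"))
  expect_equal(length(sc6$aircraft), 6)
  expect_length(sc6$conflicts, 0)
})

test_that("no unscripted pair ever loses separation", {
  for (id in c("t6_low", "t6_high", "t12_low", "t12_medium")) {
    parts <- strsplit(id, "_")[[1]]
    sc <- generate_scenario(condition(sub("t", "", parts[1]), parts[2]))
    expect_true(is.na(check_separation(sc)$time_s), label = id)
  }
  # in 12-high, every violating pair belongs to a scripted conflict
  sc <- generate_scenario(condition(12, "high"))
  conflict_ac <- c("POB456", "HYG532", "REV756", "KET456", "GPL751")
  others <- setdiff(names(sc$aircraft), conflict_ac)
  expect_true(is.na(check_separation(sc, flights = others)$time_s))
  for (a in conflict_ac)
    expect_true(is.na(check_separation(
      sc, flights = c(a, others))$time_s), label = a)
})

test_that("gaze streams satisfy the stream invariants", {
  sc <- generate_scenario(condition(6, "medium"))
  p <- cohort_params(session_seconds = 120)
  st <- simulate_gaze(sc, p, seed = 21)
  s <- st$samples
  expect_true(all(diff(s$t_ms) > 0))
  expect_equal(median(diff(s$t_ms)), 1000 / 30, tolerance = 1e-9)
  both_invalid <- !s$left_valid & !s$right_valid
  expect_true(all(is.na(s$x_cm[both_invalid])))
  expect_true(all(!is.na(s$x_cm[!both_invalid])))
})

test_that("injected blinks are recovered exactly by the detector", {
  sc <- generate_scenario(condition(6, "low"))
  p <- cohort_params(session_seconds = 300)
  for (seed in 1:5) {
    st <- simulate_gaze(sc, p, seed = seed)
    gt <- attr(st, "ground_truth")
    det <- detect_blinks(st)
    expect_equal(nrow(det$blinks), gt$n_blinks)
    expect_equal(det$blinks$start_ms, sort(gt$blink_onsets_ms),
                 tolerance = 1e-6)
  }
  # zero blink rate leaves no invalid runs
  p0 <- cohort_params(session_seconds = 120,
                      blink_rate_per_min = matrix(1e-9, 2, 3,
                                                  dimnames = list(
                                                    c("low", "high"), NULL)),
                      one_eye_invalid_rate = 0)
  st0 <- simulate_gaze(sc, p0, seed = 3)
  expect_equal(nrow(detect_blinks(st0)$blinks) +
                 nrow(detect_blinks(st0)$track_loss), 0)
})

test_that("solver logs resolve the conflicts, non-solver logs do not", {
  sc <- generate_scenario(condition(12, "high"))
  p <- cohort_params()
  for (seed in 1:6) {
    iv_s <- simulate_interventions(sc, list(easy = TRUE, difficult = TRUE),
                                   p, seed)
    expect_gte(sum(iv_s$flight == "HYG532" & iv_s$kind == "altitude"), 1)
    expect_true(classify_solver(sc, iv_s, flights = c("POB456", "HYG532")))
    expect_true(classify_solver(sc, iv_s,
                                flights = c("REV756", "KET456", "GPL751")))
    expect_gte(sum(iv_s$kind != "accept" &
                     iv_s$flight %in% c("REV756", "KET456", "GPL751")), 2)

    iv_n <- simulate_interventions(sc, list(easy = FALSE, difficult = FALSE),
                                   p, seed + 100)
    expect_false(classify_solver(sc, iv_n, flights = c("POB456", "HYG532")))
    expect_false(classify_solver(sc, iv_n,
                                 flights = c("REV756", "KET456", "GPL751")))
  }
})

test_that("solver gaze exceeds non-solver gaze on the Easy conflict", {
  sc <- generate_scenario(condition(12, "high"))
  p <- cohort_params(session_seconds = 300)
  cfg <- pipeline_config(cohort = p)
  totals <- sapply(c(TRUE, FALSE), function(sol) {
    mean(sapply(1:3, function(s) {
      solver <- list(easy = sol, difficult = FALSE)
      iv <- simulate_interventions(sc, solver, p, 500 + s)
      st <- simulate_gaze(sc, p, solver = solver, interventions = iv,
                          seed = 600 + s)
      fx <- detect_fixations(st)
      fx$aircraft <- assign_fixation_dynamic(
        fx, sc$aircraft[c("POB456", "HYG532")], dynamic_aoi_spec(), sc, iv)
      cumulative_fixation_time(fx, "POB456", c(0, 180)) +
        cumulative_fixation_time(fx, "HYG532", c(0, 180),
                                 sector_entry_s(sc$aircraft$HYG532, sc))
    }))
  })
  expect_gt(totals[1], totals[2])
})

test_that("subjective scores stay on scale and track demand", {
  p <- cohort_params()
  isa_means <- sapply(c("low", "high"), function(cx) {
    mean(sapply(1:10, function(s) {
      sc <- simulate_scores(condition(12, cx), p, seed = s)
      expect_true(all(sc$isa_ratings %in% 1:7))
      expect_true(all(sc$nasa_components %in% 1:20))
      isa_mean(sc$isa_ratings)
    }))
  })
  expect_gt(isa_means["high"], isa_means["low"])
})

test_that("the cohort generator is reproducible and complete", {
  p <- cohort_params(n_participants = 2, session_seconds = 60)
  coh <- simulate_cohort(p, seed = 5)
  expect_length(coh$sessions, 12)
  expect_equal(nrow(coh$participants), 2)
  coh2 <- simulate_cohort(p, seed = 5)
  expect_identical(coh$sessions[[3]]$stream$samples,
                   coh2$sessions[[3]]$stream$samples)
  coh3 <- simulate_cohort(p, seed = 6)
  expect_false(identical(coh$sessions[[3]]$stream$samples,
                         coh3$sessions[[3]]$stream$samples))
})
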