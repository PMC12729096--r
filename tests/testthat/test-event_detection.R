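const_stream <- function(n, invalid_at = integer(0)) {
  lv <- rep(TRUE, n)
  lv[invalid_at] <- FALSE
  make_stream(rep(30, n), rep(17, n), left_valid = lv, right_valid = lv)
}

test_that("both-eye runs inside the 100-600 ms band are blinks", {
  st <- const_stream(30, invalid_at = 10:18)          # 9 samples = 300 ms
  det <- detect_blinks(st)
  expect_equal(nrow(det$blinks), 1)
  expect_equal(det$blinks$duration_ms, 300, tolerance = 1e-9)
  expect_equal(det$blinks$start_ms, 9 * PERIOD_MS)

  # band edges are inclusive: 3 samples = 100 ms, 18 samples = 600 ms
  expect_equal(nrow(detect_blinks(const_stream(30, 10:12))$blinks), 1)
  expect_equal(nrow(detect_blinks(const_stream(40, 10:27))$blinks), 1)
})

test_that("runs outside the band are track loss, not blinks", {
  st <- const_stream(30, invalid_at = 10:11)          # 66.7 ms
  det <- detect_blinks(st)
  expect_equal(nrow(det$blinks), 0)

  st2 <- const_stream(40, invalid_at = 10:28)         # 19 samples = 633 ms
  det2 <- detect_blinks(st2)
  expect_equal(nrow(det2$blinks), 0)
  expect_equal(nrow(det2$track_loss), 1)
})

test_that("injected gaps are recovered exactly, in and out of band", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- 1500
    st <- const_stream(n)
    n_in <- sample(3:6, 1)
    n_out <- sample(1:3, 1)
    lens <- c(sample(3:18, n_in, replace = TRUE),
              sample(c(1, 2, 19, 25), n_out, replace = TRUE))
    starts <- sort(sample(seq(5, n - 30, by = 30), length(lens)))
    st <- inject_gaps(st, starts, lens)
    det <- detect_blinks(st)
    expect_equal(nrow(det$blinks), n_in)
    expect_equal(sort(det$blinks$duration_ms),
                 sort(lens[seq_len(n_in)] * PERIOD_MS), tolerance = 1e-9)
  }
})

test_that("blink output is invariant to out-of-band invalid padding", {
  st <- const_stream(60, invalid_at = 20:28)
  base <- detect_blinks(st)$blinks
  s <- st$samples
  pad <- s[rep(1, 25), ]                               # 25 samples > 600 ms
  pad$left_valid <- pad$right_valid <- FALSE
  pad$t_ms <- seq(-25, -1) * PERIOD_MS
  pad2 <- pad
  pad2$t_ms <- max(s$t_ms) + seq_len(25) * PERIOD_MS
  padded <- gaze_stream(rbind(pad, s, pad2), st$geometry)
  det <- detect_blinks(padded)
  expect_equal(det$blinks$duration_ms, base$duration_ms)
  expect_equal(det$blinks$start_ms, base$start_ms)
  expect_equal(nrow(det$track_loss), 2)
})

test_that("a steady gaze followed by a jump yields one fixation", {
  jump <- visual_angle_to_cm(5, 60)
  st <- make_stream(c(rep(30, 12), rep(30 + jump, 2)), rep(17, 14))
  fx <- detect_fixations(st)
  expect_equal(nrow(fx), 1)
  expect_equal(fx$duration_ms, 12 * PERIOD_MS, tolerance = 1e-9)
  expect_equal(fx$centroid_x_cm, 30)
  expect_equal(fx$centroid_y_cm, 17)
})

test_that("alternation beyond the dispersion bound yields no fixations", {
  d3 <- visual_angle_to_cm(3, 60)
  x <- rep(c(30, 30 + d3), 20)
  fx <- detect_fixations(make_stream(x, rep(17, 40)))
  expect_equal(nrow(fx), 0)
})

test_that("the detector matches the brute-force oracle on random walks", {
  for (seed in 1:25) {
    st <- random_walk_stream(n = 300, seed = seed)
    fx <- detect_fixations(st)
    oracle <- brute_force_idt(st)
    expect_equal(nrow(fx), nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_equal(fx$start_ms, st$samples$t_ms[oracle$start])
      expect_equal(fx$end_ms, st$samples$t_ms[oracle$end] + PERIOD_MS)
    }
  }
})

test_that("fixations never overlap blinks and stay within the record", {
  for (seed in 1:10) {
    st <- random_walk_stream(n = 400, seed = seed + 100)
    fx <- detect_fixations(st)
    det <- detect_blinks(st)
    gaps <- rbind(det$blinks, det$track_loss)
    if (nrow(fx) > 0 && nrow(gaps) > 0) {
      for (i in seq_len(nrow(gaps)))
        expect_true(all(fx$end_ms <= gaps$start_ms[i] + 1e-9 |
                          fx$start_ms >= gaps$end_ms[i] - 1e-9))
    }
    total <- nrow(st$samples) * PERIOD_MS
    expect_lte(sum(fx$duration_ms), total + 1e-9)
    if (nrow(fx) > 1) {
      expect_true(all(diff(fx$start_ms) > 0))
      expect_true(all(fx$start_ms[-1] >= fx$end_ms[-nrow(fx)] - 1e-9))
    }
  }
})

test_that("pupil summaries average the available eyes", {
  st <- make_stream(rep(30, 10), rep(17, 10), pupil = rep(3.44, 10))
  expect_equal(pupil_mean(st), 3.44)

  s <- st$samples
  s$pupil_left_mm <- 3
  s$pupil_right_mm <- 4
  expect_equal(pupil_mean(gaze_stream(s, st$geometry)), 3.5)

  s2 <- st$samples
  s2$left_valid <- s2$right_valid <- FALSE
  st2 <- suppressWarnings(gaze_stream(s2, st$geometry))
  expect_warning(pm <- pupil_mean(st2), "no valid pupil")
  expect_true(is.na(pm))
})

test_that("blink statistics summarise count and mean duration", {
  expect_equal(blink_stats(data.frame(duration_ms = numeric(0)))$count, 0)
  expect_true(is.na(blink_stats(data.frame(
    duration_ms = numeric(0)))$mean_duration_ms))
  bs <- blink_stats(data.frame(duration_ms = c(200, 400)))
  expect_equal(bs$count, 2)
  expect_equal(bs$mean_duration_ms, 300)
})

test_that("simulated high-traffic pupil matches the generator baseline", {
  sc <- generate_scenario(condition(12, "medium"))
  p <- cohort_params(session_seconds = 240)
  st <- simulate_gaze(sc, p, seed = 11)
  # no participant offset: session mean within 2 SE-ish of the 3.44 baseline
  expect_lt(abs(pupil_mean(st) - 3.44), 0.1)
})
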