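geom <- screen_geometry()
aois <- build_static_aois(geom)

fix_at <- function(x, y, dur_ms = 300, start_ms = 0) {
  data.frame(start_ms = start_ms, end_ms = start_ms + dur_ms,
             duration_ms = dur_ms, centroid_x_cm = x, centroid_y_cm = y,
             n_samples = round(dur_ms / PERIOD_MS))
}

test_that("the static AOIs tile the display as specified", {
  expect_equal(aois$sector$left_cm, (61 - 27.5) / 2)
  expect_equal(aois$sector$left_cm, 16.75)
  expect_equal(aois$sector$top_cm, (34 - 20.5) / 2)
  expect_equal(aois$sheet$left_cm, 61 - 17)
  expect_equal(aois$sheet$top_cm, 0)
  # the sector subtends the printed visual angles at 60 cm
  expect_equal(round(cm_to_visual_angle(aois$sector$width_cm, 60), 2), 25.81)
  expect_equal(round(cm_to_visual_angle(aois$sector$height_cm, 60), 2), 19.39)
  expect_error(build_static_aois(screen_geometry(display_width_cm = 20)),
               "too small")
})

test_that("centroid assignment follows containment and precedence", {
  expect_equal(assign_fixation_static(fix_at(30.5, 17), aois), "sector")
  expect_equal(assign_fixation_static(fix_at(50, 3), aois), "sheet")
  expect_equal(assign_fixation_static(fix_at(1, 33), aois), "out_of_sector")
  expect_equal(assign_fixation_static(fix_at(0, 0), aois), "out_of_sector")
  expect_equal(assign_fixation_static(fix_at(-1, 17), aois), "off_display")
  # closed left/top edge, open right/bottom edge
  expect_equal(assign_fixation_static(fix_at(16.75, 6.75), aois), "sector")
  expect_equal(assign_fixation_static(fix_at(16.75 + 27.5, 17), aois),
               "out_of_sector")
  # sheet precedence over the sector strip it touches
  expect_equal(assign_fixation_static(fix_at(44.1, 7.0), aois), "sheet")
})

test_that("static AOI fixation time is conserved exactly", {
  set.seed(5)
  fx <- do.call(rbind, lapply(1:200, function(i)
    fix_at(runif(1, -2, 63), runif(1, -2, 36), dur_ms = runif(1, 100, 800),
           start_ms = i * 1000)))
  lab <- assign_fixation_static(fx, aois)
  expect_equal(length(lab), nrow(fx))
  expect_true(all(lab %in% c("sector", "out_of_sector", "sheet",
                             "off_display")))
  on_display <- lab != "off_display"
  expect_equal(sum(fx$duration_ms[lab == "sector"]) +
                 sum(fx$duration_ms[lab == "out_of_sector"]) +
                 sum(fx$duration_ms[lab == "sheet"]),
               sum(fx$duration_ms[on_display]))
})

lin_traj <- function(flight = "AAA111", x0 = -10, y0 = 0, vx = 0.1, vy = 0,
                     alt = 30000, dur = 960) {
  trajectory(flight, data.frame(
    t_s = c(0, dur), x_nm = c(x0, x0 + vx * dur), y_nm = c(y0, y0 + vy * dur),
    alt_ft = c(alt, alt), gs_kn = sqrt(vx^2 + vy^2) * 3600))
}

scn <- function(trajs, dur = 960) {
  structure(list(condition = condition(6, "low"), duration_s = dur,
                 aircraft = trajs, conflicts = list(),
                 viewport = make_viewport(geom), geometry = geom),
            class = "scenario")
}

test_that("dynamic AOIs track the aircraft with constant size", {
  spec <- dynamic_aoi_spec(3, 2)
  stat <- scn(list(A = lin_traj("A", vx = 0)))
  r1 <- dynamic_aoi_at(stat$aircraft$A, 0, spec, stat)
  r2 <- dynamic_aoi_at(stat$aircraft$A, 500000, spec, stat)
  expect_equal(r1[c("left_cm", "top_cm")], r2[c("left_cm", "top_cm")])

  mov <- scn(list(A = lin_traj("A", vx = 0.1)))
  ra <- dynamic_aoi_at(mov$aircraft$A, 0, spec, mov)
  rb <- dynamic_aoi_at(mov$aircraft$A, 100000, spec, mov)
  rc <- dynamic_aoi_at(mov$aircraft$A, 200000, spec, mov)
  # centre interpolates linearly; area constant
  expect_equal(rb$left_cm - ra$left_cm, rc$left_cm - rb$left_cm,
               tolerance = 1e-9)
  expect_equal(ra$width_cm * ra$height_cm, rc$width_cm * rc$height_cm)
  expect_error(dynamic_aoi_at(mov$aircraft$A, 1e9, spec, mov), "time span")
})

test_that("automated tracking reproduces hand-placed rectangles", {
  spec <- dynamic_aoi_spec(3, 2)
  vx <- 0.12
  mov <- scn(list(A = lin_traj("A", x0 = -20, y0 = 5, vx = vx)))
  vp <- mov$viewport
  for (t_s in c(0, 100, 250, 400)) {
    r <- dynamic_aoi_at(mov$aircraft$A, t_s * 1000, spec, mov)
    hand_x <- geom$display_width_cm / 2 + (-20 + vx * t_s) *
      vp$scale_cm_per_nm - 1.5
    hand_y <- geom$display_height_cm / 2 - 5 * vp$scale_cm_per_nm - 1
    expect_lt(abs(r$left_cm - hand_x), 0.1)
    expect_lt(abs(r$top_cm - hand_y), 0.1)
  }
})

test_that("fixations are assigned to the dominant dynamic AOI", {
  spec <- dynamic_aoi_spec(3, 2)
  sc <- scn(list(A = lin_traj("A", x0 = 0, vx = 0), B = lin_traj("B", x0 = 20, vx = 0)))
  pa <- project_to_screen(sc$viewport, 0, 0)
  glued <- fix_at(pa$x_cm, pa$y_cm, dur_ms = 500, start_ms = 1000)
  expect_equal(assign_fixation_dynamic(glued, sc$aircraft, spec, sc), "A")
  far <- fix_at(5, 30, dur_ms = 500, start_ms = 1000)
  expect_true(is.na(assign_fixation_dynamic(far, sc$aircraft, spec, sc)))
  expect_equal(assign_fixation_dynamic(glued, list(), spec, sc),
               NA_character_)
})

test_that("split overlap goes to the aircraft covering more of the fixation", {
  spec <- dynamic_aoi_spec(3, 2)
  # A sits on the fixation point for the whole fixation; B flies through,
  # covering it for ~30% of the duration
  vp <- make_viewport(geom)
  speed_nm_s <- (3 / vp$scale_cm_per_nm) / 3   # crosses its own AOI in ~3 s
  scB <- scn(list(
    A = lin_traj("A", x0 = 0, y0 = 0, vx = 0),
    B = lin_traj("B", x0 = -speed_nm_s * 5, y0 = 0, vx = speed_nm_s)))
  pa <- project_to_screen(vp, 0, 0)
  fx <- fix_at(pa$x_cm, pa$y_cm, dur_ms = 10000, start_ms = 0)
  expect_equal(assign_fixation_dynamic(fx, scB$aircraft, spec, scB), "A")
})

test_that("cumulative fixation time clips to the window and sector entry", {
  fx <- rbind(fix_at(1, 1, dur_ms = 4000, start_ms = 10000),
              fix_at(1, 1, dur_ms = 6000, start_ms = 50000),
              fix_at(1, 1, dur_ms = 2000, start_ms = 100000))
  fx$aircraft <- c("HYG532", "HYG532", "POB456")
  expect_equal(cumulative_fixation_time(fx, "HYG532", c(0, 120)), 10)
  expect_equal(cumulative_fixation_time(fx, "ZZZ", c(0, 120)), 0)
  # half-in-window fixation counts half
  expect_equal(cumulative_fixation_time(fx, "HYG532", c(0, 53)), 7)
  # sector entry clips the window start
  expect_equal(cumulative_fixation_time(fx, "HYG532", c(0, 120),
                                        sector_entry_s = 50), 6)
})

test_that("a constructed fixture reproduces an 18.29 s cumulative total", {
  durs <- c(rep(2000, 9), 290)                  # 18.29 s in total
  fx <- do.call(rbind, lapply(seq_along(durs), function(i)
    fix_at(1, 1, dur_ms = durs[i], start_ms = 3000 * i)))
  fx$aircraft <- "HYG532"
  expect_equal(cumulative_fixation_time(fx, "HYG532", c(0, 60)), 18.29)
})

test_that("sliding-window attention shares are exact ratios", {
  fx <- fix_at(1, 1, dur_ms = 10000, start_ms = 0)
  fx$aircraft <- "A"
  att <- sliding_window_attention(fx, "A", t_end_ms = 30000)
  expect_equal(att$A[1], 100)                  # window fully covered at t = 10 s
  expect_equal(att$A[nrow(att)], 0)            # empty window at t = 30 s
  i_half <- which.min(abs(att$t_ms - 15000))
  expect_equal(att$A[i_half], 50, tolerance = 0.5)
  expect_true(all(att$A >= 0 & att$A <= 100))
  expect_equal(att$total, att$A)
  expect_error(sliding_window_attention(fx, "A", t_end_ms = 5000),
               "shorter")
})
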