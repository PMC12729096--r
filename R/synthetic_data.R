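#' Cohort generator parameters
#'
#' Generative parameters of the synthetic study: 24 participants x 6
#' counterbalanced conditions (2 traffic x 3 complexity), 16-min sessions at
#' 30 Hz. Defaults encode the study conditions the analysis expects: pupil
#' baselines of 3.41 mm (six aircraft) and 3.44 mm (twelve aircraft) with a
#' 0.32 mm between-participant SD, blink rates decreasing with traffic and
#' with high complexity, blink durations around 315 ms (low traffic) and
#' 295 ms (high traffic), an attention policy allocating roughly 83/13/4% of
#' fixation time to sector/out-of-sector/sheet at medium complexity, solver
#' proportions of 8/24 (Easy conflict) and 13/24 (Difficult), and conflict
#' gaze budgets calibrated to the solver/non-solver cumulative fixation
#' times of the two scripted conflicts (35.67 vs 16.11 s Easy; 68.56 vs
#' 81.50 s Difficult).
#'
#' @param n_participants Number of participants (default 24).
#' @param session_seconds Recorded session length in seconds (default 960).
#'   Scenarios are always scripted over the full 960 s; shorter values
#'   truncate the recording only.
#' @param zero_effects If `TRUE`, every condition-dependent parameter is
#'   flattened to its grand value, giving a null cohort for type-I-error
#'   calibration.
#' @param ... Named overrides for any default listed below.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 24, session_seconds = 960,
                          zero_effects = FALSE, ...) {
  p <- list(
    n_participants = n_participants,
    session_seconds = session_seconds,
    # pupil model (mm)
    pupil_base_mm = c(low = 3.41, high = 3.44),
    pupil_between_sd = 0.32,
    pupil_session_sd = 0.03,
    pupil_ar1 = 0.97,
    pupil_ar_sd = 0.08,
    pupil_meas_sd = 0.02,
    pupil_eye_gap_mm = 0.10,
    # blink model; rows = traffic (low, high), cols = complexity
    blink_rate_per_min = rbind(low = c(13, 12.5, 11.5),
                               high = c(9.5, 9.2, 8.3)),
    blink_rate_participant_sd_log = 0.25,
    blink_dur_mean_ms = c(low = 315, high = 295),
    blink_dur_sd_ms = 60,
    # fixation renewal process
    fixation_mean_ms = 300,
    fixation_shape = 4,
    fixation_min_samples = 4,
    saccade_samples = c(1, 2),
    fixation_jitter_cm = 0.03,
    one_eye_invalid_rate = 0.01,
    # attention policy
    sector_share = c(low = 0.78, medium = 0.83, high = 0.88),
    sheet_share = c(low = 0.05, high = 0.03),
    aircraft_share_of_sector = 0.65,
    # conflict gaze budgets (cumulative seconds over the analysis windows)
    easy_target_s = c(solver = 35.67, nonsolver = 16.11),
    difficult_target_s = c(solver = 68.56, nonsolver = 81.50),
    solver_p = c(easy = 8 / 24, difficult = 13 / 24),
    # subjective scores; rows = traffic, cols = complexity
    isa_cond_mean = rbind(low = c(2.8, 3.3, 3.45),
                          high = c(4.4, 4.9, 5.05)),
    isa_participant_sd = 0.6,
    isa_rating_sd = 0.8,
    nasa_cond_mean = rbind(low = c(45, 50, 52),
                           high = c(63, 68, 70)),
    nasa_participant_sd = 8,
    nasa_component_sd = 2.5,
    # head distance (cm)
    head_distance_cm = 59,
    head_participant_sd = 1,
    head_within_sd = 0.3,
    accept_delay_mean_s = 12)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0)
    stop("unknown cohort parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  if (zero_effects) {
    p$pupil_base_mm[] <- mean(p$pupil_base_mm)
    p$blink_rate_per_min[] <- mean(p$blink_rate_per_min)
    p$blink_dur_mean_ms[] <- mean(p$blink_dur_mean_ms)
    p$sector_share[] <- mean(p$sector_share)
    p$sheet_share[] <- mean(p$sheet_share)
    p$isa_cond_mean[] <- mean(p$isa_cond_mean)
    p$nasa_cond_mean[] <- mean(p$nasa_cond_mean)
    p$easy_target_s[] <- mean(p$easy_target_s)
    p$difficult_target_s[] <- mean(p$difficult_target_s)
  }
  stopifnot(p$n_participants >= 1,
            all(p$blink_rate_per_min > 0),
            all(p$solver_p >= 0 & p$solver_p <= 1),
            all(p$blink_dur_mean_ms > 100 & p$blink_dur_mean_ms < 600),
            all(p$sector_share + max(p$sheet_share) < 1))
  class(p) <- "cohort_params"
  p
}

# deterministic per-session RNG substream
session_seed <- function(seed, participant, condition_index) {
  as.integer((as.numeric(seed) + 7919 * participant +
                104729 * condition_index) %% 2147483647)
}

#' Schedule a two-aircraft conflict that violates separation at a set time
#'
#' Places a level aircraft and a climbing aircraft on converging straight
#' tracks so that, left unresolved, the pair first violates the separation
#' minima (lateral and vertical simultaneously below threshold) at the
#' target time on the scan grid. Both aircraft reach the crossing point at
#' the same instant; the climber's initial altitude is set so the vertical
#' minimum is crossed `vert_margin_s` seconds before the lateral one. The
#' schedule is verified by forward simulation with [check_separation()].
#'
#' @param target_violation_s Scripted first-violation time (s).
#' @param flights Length-2 labels: c(level aircraft, climbing aircraft).
#' @param speeds_kn Length-2 ground speeds (kn).
#' @param crossing_angle_deg Angle between the two tracks (degrees).
#' @param heading1_deg Track of the level aircraft (degrees, 0 = east,
#'   counter-clockwise).
#' @param level_alt_ft Cruise level of the level aircraft; the climber
#'   levels off there.
#' @param climb_rate_ft_min Climb rate of the second aircraft.
#' @param conflict_point_nm Length-2 crossing point in sector NM.
#' @param duration_s Scenario span (default 960 s).
#' @param standard A [separation_standard()].
#' @param grid_s Verification grid step (default 1 s).
#' @param vert_margin_s Seconds before the target at which the vertical
#'   minimum is crossed (default 30).
#' @return List with `trajectories` (two [trajectory()]s) and
#'   `violation_s` (the verified first-violation time).
#' @export
schedule_conflict <- function(target_violation_s, flights, speeds_kn,
                              crossing_angle_deg, heading1_deg = 0,
                              level_alt_ft = 35000,
                              climb_rate_ft_min = 1500,
                              conflict_point_nm = c(0, 0),
                              duration_s = 960,
                              standard = separation_standard(),
                              grid_s = 1, vert_margin_s = 30) {
  stopifnot(target_violation_s > 0, length(flights) == 2,
            length(speeds_kn) == 2)
  h1 <- heading1_deg * pi / 180
  h2 <- (heading1_deg + crossing_angle_deg) * pi / 180
  u1 <- c(cos(h1), sin(h1))
  u2 <- c(cos(h2), sin(h2))
  v <- speeds_kn / 3600                       # NM/s
  rel <- v[1] * u1 - v[2] * u2
  w <- sqrt(sum(rel^2))
  if (w < 1e-9)
    stop("non-closing geometry: tracks have identical velocity",
         call. = FALSE)
  t_c <- (target_violation_s - grid_s / 2) + standard$lateral_min_nm / w
  rate <- climb_rate_ft_min / 60              # ft/s
  margin <- min(vert_margin_s, 0.7 * target_violation_s)
  a0 <- level_alt_ft - standard$vertical_min_ft -
    rate * (target_violation_s - margin - grid_s / 2)
  if (a0 >= level_alt_ft)
    stop("infeasible climb profile for the requested violation time",
         call. = FALSE)
  t_cap <- (level_alt_ft - a0) / rate
  p1 <- conflict_point_nm - v[1] * t_c * u1
  p2 <- conflict_point_nm - v[2] * t_c * u2
  wp <- function(p0, u, vv, alts, t_alts) {
    ts <- sort(unique(c(0, t_alts, duration_s)))
    ts <- ts[ts <= duration_s]
    data.frame(t_s = ts,
               x_nm = p0[1] + vv * ts * u[1],
               y_nm = p0[2] + vv * ts * u[2],
               alt_ft = stats::approx(c(0, t_alts, duration_s + 1),
                                      c(alts[1], alts[-1],
                                        alts[length(alts)]),
                                      ts, rule = 2)$y,
               gs_kn = vv * 3600)
  }
  tr1 <- trajectory(flights[1],
                    wp(p1, u1, v[1], c(level_alt_ft, level_alt_ft),
                       duration_s / 2),
                    route_class = "standard",
                    vertical_rate_ft_min = climb_rate_ft_min)
  tr2 <- trajectory(flights[2],
                    wp(p2, u2, v[2], c(a0, level_alt_ft),
                       min(t_cap, duration_s - 1)),
                    route_class = "non-standard",
                    vertical_rate_ft_min = climb_rate_ft_min)
  mini <- list(aircraft = stats::setNames(list(tr1, tr2), flights),
               duration_s = duration_s)
  got <- check_separation(mini, standard = standard, grid_s = grid_s)$time_s
  if (is.na(got) || abs(got - target_violation_s) > grid_s)
    stop(sprintf("scheduling failed: violation at %s s, target %s s",
                 got, target_violation_s), call. = FALSE)
  list(trajectories = stats::setNames(list(tr1, tr2), flights),
       violation_s = got)
}

filler_trajectory <- function(name, y_nm, eastbound, speed_kn, alt_ft,
                              duration_s, x_edge = 66) {
  x0 <- if (eastbound) -x_edge else x_edge
  u <- if (eastbound) 1 else -1
  v <- speed_kn / 3600
  trajectory(name, data.frame(
    t_s = c(0, duration_s),
    x_nm = c(x0, x0 + u * v * duration_s),
    y_nm = c(y_nm, y_nm),
    alt_ft = c(alt_ft, alt_ft),
    gs_kn = speed_kn))
}

#' Generate a scripted traffic scenario for one condition
#'
#' Builds the 960 s scenario for a traffic x complexity condition. The
#' twelve-aircraft high-complexity scenario embeds the two scripted
#' conflicts: the Easy conflict (POB456 level on a standard route, HYG532
#' climbing on a non-standard trajectory; first violation 140 s after
#' onset if unresolved) and the Difficult conflict (KET456 and GPL751 on
#' standard routes, REV756 climbing on a non-standard trajectory; first
#' violation at 240 s), plus the look-alike non-conflict flight SRT346 and
#' six background aircraft. All other scenarios contain only background
#' aircraft on mutually safe flight levels, so no unscripted loss of
#' separation can occur.
#'
#' @param cond A [condition()].
#' @param geometry A [screen_geometry()].
#' @param duration_s Scenario span in seconds (default 960).
#' @param seed Optional seed jittering background ground speeds.
#' @return A list of class `scenario`: `condition`, `duration_s`,
#'   `aircraft` (named list of [trajectory()]), `conflicts` (list of
#'   [conflict_spec()]), `viewport`, `geometry`.
#' @export
generate_scenario <- function(cond, geometry = screen_geometry(),
                              duration_s = 960, seed = NULL) {
  vp <- make_viewport(geometry)
  aircraft <- list()
  conflicts <- list()
  is_12high <- cond$traffic == 12L && cond$complexity == "high"
  n_filler <- cond$traffic - if (is_12high) 6L else 0L
  if (is_12high) {
    easy <- schedule_conflict(140, c("POB456", "HYG532"),
                              speeds_kn = c(450, 430),
                              crossing_angle_deg = 60, heading1_deg = 0,
                              level_alt_ft = 35000,
                              conflict_point_nm = c(-5, -10),
                              duration_s = duration_s)
    difficult <- schedule_conflict(240, c("KET456", "REV756"),
                                   speeds_kn = c(460, 420),
                                   crossing_angle_deg = -30,
                                   heading1_deg = 180,
                                   level_alt_ft = 33000,
                                   conflict_point_nm = c(10, 8),
                                   duration_s = duration_s)
    gpl_u <- c(-4, -28) / sqrt(4^2 + 28^2)
    gpl_v <- 440 / 3600
    gpl <- trajectory("GPL751", data.frame(
      t_s = c(0, duration_s),
      x_nm = 14 + gpl_u[1] * gpl_v * c(0, duration_s),
      y_nm = 36 + gpl_u[2] * gpl_v * c(0, duration_s),
      alt_ft = c(37000, 37000), gs_kn = 440))
    srt_u <- c(0.894, -0.447)
    srt_v <- 410 / 3600
    srt <- trajectory("SRT346", data.frame(
      t_s = c(0, 160, duration_s),
      x_nm = -35 + srt_u[1] * srt_v * c(0, 160, duration_s),
      y_nm = 25 + srt_u[2] * srt_v * c(0, 160, duration_s),
      alt_ft = c(27000, 31000, 31000), gs_kn = 410),
      route_class = "non-standard")
    aircraft <- c(easy$trajectories, difficult$trajectories,
                  list(GPL751 = gpl, SRT346 = srt))
    conflicts <- list(
      easy = conflict_spec("easy", c("POB456", "HYG532"), 140, c(0, 180)),
      difficult = conflict_spec("difficult", c("REV756", "KET456", "GPL751"),
                                240, c(0, 300)))
  }
  filler_rows <- c(30, -30, -18, 18, 6, -6, 33, -33, 12, -12, 24, -24)
  filler_speed <- c(430, 450, 420, 460, 440, 435, 425, 455, 445, 415, 465,
                    410)
  if (!is.null(seed)) {
    set.seed(seed)
    filler_speed <- filler_speed + sample(-10:10, length(filler_speed),
                                          replace = TRUE)
  }
  if (n_filler > 0) {
    base_level <- 38000
    for (k in seq_len(n_filler)) {
      name <- sprintf("BGD%03d", k)
      aircraft[[name]] <- filler_trajectory(
        name, filler_rows[k], eastbound = (k %% 2 == 1), filler_speed[k],
        base_level + 1000 * (k - 1), duration_s)
    }
  }
  structure(list(condition = cond, duration_s = duration_s,
                 aircraft = aircraft, conflicts = conflicts,
                 viewport = vp, geometry = geometry),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: %d aircraft, %d scripted conflict(s), %g s\n",
              x$condition$id, length(x$aircraft), length(x$conflicts),
              x$duration_s))
  invisible(x)
}

traffic_label <- function(cond) if (cond$traffic == 6L) "low" else "high"

# expected fraction of wall-clock time spent in detected fixations
duty_cycle <- function(params, blink_rate_min, blink_mean_ms) {
  period <- 1000 / 30
  sacc <- mean(params$saccade_samples) * period
  fix_share <- params$fixation_mean_ms / (params$fixation_mean_ms + sacc)
  blink_loss <- (blink_rate_min / 60) * (blink_mean_ms / 1000)
  fix_share * (1 - blink_loss)
}

#' Simulate the controller's clearances for one 12-high session
#'
#' Solver logs contain clearances that keep the scripted conflicts above the
#' separation minima (an altitude clearance stopping the climb of the
#' non-standard flight, plus at least one further intervention for the
#' Difficult conflict); non-solver logs are empty or contain only
#' post-violation (ineffective) actions. Acceptance actions for the
#' sector-entering flights are always logged.
#'
#' @param scenario The 12-high scenario.
#' @param solver List with logical `easy` and `difficult`.
#' @param params A [cohort_params()].
#' @param seed RNG seed.
#' @return Intervention log data.frame: `t_s`, `flight`, `kind`, `value`.
#' @export
simulate_interventions <- function(scenario, solver, params, seed) {
  set.seed(seed)
  rows <- list()
  add <- function(t_s, flight, kind, value = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      t_s = t_s, flight = flight, kind = kind, value = value)
  }
  for (fl in c("HYG532", "REV756")) {
    if (fl %in% names(scenario$aircraft)) {
      entry <- sector_entry_s(scenario$aircraft[[fl]], scenario)
      if (!is.na(entry))
        add(entry + max(2, stats::rnorm(1, params$accept_delay_mean_s, 6)),
            fl, "accept")
    }
  }
  if (length(scenario$conflicts) > 0) {
    if (isTRUE(solver$easy)) {
      add(stats::runif(1, 60, 110), "HYG532", "altitude", 32000)
      if (stats::runif(1) < 0.25)
        add(stats::runif(1, 70, 120), "POB456", "altitude", 36000)
    } else if (stats::runif(1) < 0.06) {
      add(stats::runif(1, 150, 175), "POB456", "altitude", 36000)
    }
    if (isTRUE(solver$difficult)) {
      t0 <- stats::runif(1, 140, 200)
      add(t0, "REV756", "altitude", 30000)
      second <- sample(c("speed_REV", "speed_KET", "alt_GPL"), 1)
      t2 <- stats::runif(1, t0 + 15, 260)
      switch(second,
             speed_REV = add(t2, "REV756", "speed", 390),
             speed_KET = add(t2, "KET456", "speed", 430),
             alt_GPL = add(t2, "GPL751", "altitude", 36000))
      if (stats::runif(1) < 0.15)
        add(stats::runif(1, 265, 300), "GPL751", "speed", 420)
    } else if (stats::runif(1) < 0.7) {
      if (stats::runif(1) < 0.5) {
        add(stats::runif(1, 250, 300), "KET456", "speed", 440)
      } else {
        add(stats::runif(1, 250, 300), "GPL751", "altitude", 36000)
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(t_s = numeric(0), flight = character(0),
                      kind = character(0), value = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$t_s), , drop = FALSE]
}

#' Simulate a 30 Hz gaze stream for one session
#'
#' Renewal process over fixation targets: fixation durations are gamma
#' distributed (mean 300 ms), separated by 1--2 transit samples; targets are
#' drawn over aircraft, sector background, out-of-sector airspace and the
#' flight-plan sheet with condition-dependent weights. In the 12-high
#' scenario the conflict aircraft receive a gaze budget over the conflict
#' analysis windows calibrated so the expected cumulative fixation time
#' matches the solver/non-solver targets. Blinks are injected as both-eye
#' invalid gaps (Poisson arrivals, truncated-normal durations inside the
#' 100--600 ms band); pupil diameter is the condition baseline plus AR(1)
#' noise.
#'
#' @param scenario A [generate_scenario()] result.
#' @param params A [cohort_params()].
#' @param participant List of participant effects (`pupil_offset_mm`,
#'   `blink_rate_mult`, `head_offset_cm`); defaults to zero effects.
#' @param solver List with logical `easy`, `difficult` (drives conflict
#'   gaze boosts in the 12-high scenario).
#' @param interventions Intervention log applied to the displayed traffic.
#' @param seed RNG seed.
#' @param participant_id,condition_id Labels for the stream.
#' @return A [gaze_stream()]; attribute `"ground_truth"` carries the
#'   injected blink onsets/durations and target labels.
#' @export
simulate_gaze <- function(scenario, params,
                          participant = list(pupil_offset_mm = 0,
                                             blink_rate_mult = 1,
                                             head_offset_cm = 0),
                          solver = list(easy = FALSE, difficult = FALSE),
                          interventions = NULL, seed = 1,
                          participant_id = "P01",
                          condition_id = scenario$condition$id) {
  set.seed(seed)
  geometry <- scenario$geometry
  period <- sample_period_ms(geometry)
  n_total <- round(params$session_seconds * geometry$sampling_rate_hz)
  tl <- traffic_label(scenario$condition)
  cl <- scenario$condition$complexity
  aois <- build_static_aois(geometry)

  # aircraft screen positions and visibility on a 1 s grid
  grid_s <- seq(0, scenario$duration_s, by = 1)
  labels <- names(scenario$aircraft)
  posx <- posy <- matrix(NA_real_, length(grid_s), length(labels),
                         dimnames = list(NULL, labels))
  for (a in labels) {
    pp <- screen_position(scenario$aircraft[[a]], grid_s, scenario$viewport,
                          interventions)
    posx[, a] <- pp$x_cm
    posy[, a] <- pp$y_cm
  }
  visible <- posx >= 0.5 & posx <= geometry$display_width_cm - 0.5 &
    posy >= 0.5 & posy <= geometry$display_height_cm - 0.5
  visible[is.na(visible)] <- FALSE
  sec <- build_static_aois(geometry)$sector
  in_sector <- posx >= sec$left_cm & posx < sec$left_cm + sec$width_cm &
    posy >= sec$top_cm & posy < sec$top_cm + sec$height_cm
  in_sector[is.na(in_sector)] <- FALSE

  # attention weights
  blink_rate <- params$blink_rate_per_min[tl, match(cl, c("low", "medium",
                                                          "high"))] *
    participant$blink_rate_mult
  duty <- duty_cycle(params, blink_rate, params$blink_dur_mean_ms[tl])
  w_sector <- params$sector_share[[cl]]
  w_sheet <- params$sheet_share[[tl]]
  w_out <- 1 - w_sector - w_sheet
  easy_ac <- c("POB456", "HYG532")
  diff_ac <- c("REV756", "KET456", "GPL751")
  has_conflicts <- length(scenario$conflicts) > 0
  w_easy <- w_diff <- 0
  if (has_conflicts) {
    eff_len <- function(ac, win) {
      mean(vapply(ac, function(a) {
        entry <- sector_entry_s(scenario$aircraft[[a]], scenario)
        win[2] - max(win[1], if (is.na(entry)) win[1] else entry)
      }, numeric(1)))
    }
    easy_win <- scenario$conflicts$easy$window_s
    diff_win <- scenario$conflicts$difficult$window_s
    w_easy <- params$easy_target_s[[if (isTRUE(solver$easy)) "solver"
                                    else "nonsolver"]] /
      (duty * eff_len(easy_ac, easy_win))
    w_diff <- params$difficult_target_s[[if (isTRUE(solver$difficult))
      "solver" else "nonsolver"]] / (duty * eff_len(diff_ac, diff_win))
    # monitoring inbound conflict traffic happens outside the sector until
    # each aircraft's entry; that expected time is part of the out-of-sector
    # budget, so deduct it from the free out-of-sector weight
    pre_entry <- function(ac, win) {
      mean(vapply(ac, function(a) {
        entry <- sector_entry_s(scenario$aircraft[[a]], scenario)
        if (is.na(entry)) 0 else max(0, min(entry, win[2]) - win[1])
      }, numeric(1)))
    }
    out_monitor <- (w_easy * pre_entry(easy_ac, easy_win) +
                      w_diff * pre_entry(diff_ac, diff_win)) /
      params$session_seconds
    w_out <- max(0.02, w_out - out_monitor)
  }

  # --- build the valid-sample trace (vectorised renewal process) ---
  total_ms <- n_total * period
  n_ev <- ceiling(total_ms / (params$fixation_min_samples * period)) + 10L
  k_fix <- pmax(params$fixation_min_samples,
                round(stats::rgamma(n_ev, shape = params$fixation_shape,
                                    scale = params$fixation_mean_ms /
                                      params$fixation_shape) / period))
  n_sac <- sample(params$saccade_samples, n_ev, replace = TRUE)
  n_sac[1] <- 0L
  block <- n_sac + k_fix
  keep_n <- which(cumsum(block) >= n_total)[1]
  k_fix <- k_fix[seq_len(keep_n)]
  n_sac <- n_sac[seq_len(keep_n)]
  block <- block[seq_len(keep_n)]
  ev_start <- cumsum(c(1, block[-keep_n]))          # first sample of block
  ev_t_s <- (ev_start - 1) * period / 1000

  # target category per event (weights change only at the window edges)
  gi <- pmin(length(grid_s), floor(ev_t_s) + 1L)
  we <- if (has_conflicts)
    w_easy * (ev_t_s < scenario$conflicts$easy$window_s[2]) else
      numeric(keep_n)
  wd <- if (has_conflicts)
    w_diff * (ev_t_s < scenario$conflicts$difficult$window_s[2]) else
      numeric(keep_n)
  w_rest <- pmax(0.02, w_sector - we - wd)
  w_air <- params$aircraft_share_of_sector * w_rest
  w_bg <- w_rest - w_air
  wmat <- cbind(we, wd, w_air, w_bg, w_out, w_sheet)
  cw <- wmat / rowSums(wmat)
  cw <- t(apply(cw, 1, cumsum))
  cat_i <- rowSums(stats::runif(keep_n) > cw) + 1L

  other_ac <- setdiff(labels, c(if (has_conflicts) c(easy_ac, diff_ac)))
  ev_lab <- rep("bg", keep_n)
  pick_among <- function(idx, ac_set, where) {
    if (length(idx) == 0 || length(ac_set) == 0) return()
    lab <- ac_set[sample.int(length(ac_set), length(idx), replace = TRUE)]
    ok <- where[cbind(gi[idx], match(lab, labels))]
    ev_lab[idx[ok]] <<- lab[ok]
    cat_i[idx[!ok]] <<- 4L                   # fall back to background
  }
  # conflict aircraft are monitored anywhere on screen; ordinary traffic is
  # only looked at while inside the active sector
  pick_among(which(cat_i == 1L), easy_ac, visible)
  pick_among(which(cat_i == 2L), diff_ac, visible)
  pick_among(which(cat_i == 3L), other_ac, in_sector)
  ev_lab[cat_i == 5L] <- "out"
  ev_lab[cat_i == 6L] <- "sheet"

  ev_x <- ev_y <- numeric(keep_n)
  is_ac <- cat_i <= 3L & ev_lab %in% labels
  if (any(is_ac)) {
    ij <- cbind(gi[is_ac], match(ev_lab[is_ac], labels))
    ev_x[is_ac] <- posx[ij] + stats::runif(sum(is_ac), -1, 1)
    ev_y[is_ac] <- posy[ij] + stats::runif(sum(is_ac), -0.6, 0.6)
  }
  bg_i <- which(cat_i == 4L)
  ev_lab[bg_i] <- "bg"
  ev_x[bg_i] <- stats::runif(length(bg_i), aois$sector$left_cm + 0.5,
                             aois$sector$left_cm + aois$sector$width_cm - 0.5)
  ev_y[bg_i] <- stats::runif(length(bg_i), aois$sector$top_cm + 0.5,
                             aois$sector$top_cm + aois$sector$height_cm - 0.5)
  out_i <- which(cat_i == 5L)
  while (length(out_i) > 0) {                # rejection-sample the complement
    xx <- stats::runif(length(out_i), 0.3, geometry$display_width_cm - 0.3)
    yy <- stats::runif(length(out_i), 0.3, geometry$display_height_cm - 0.3)
    ok <- !point_in_rect(xx, yy, aois$sector) &
      !point_in_rect(xx, yy, aois$sheet)
    ev_x[out_i[ok]] <- xx[ok]
    ev_y[out_i[ok]] <- yy[ok]
    out_i <- out_i[!ok]
  }
  sh_i <- which(cat_i == 6L)
  ev_x[sh_i] <- stats::runif(length(sh_i), aois$sheet$left_cm + 0.5,
                             aois$sheet$left_cm + aois$sheet$width_cm - 0.5)
  ev_y[sh_i] <- stats::runif(length(sh_i), aois$sheet$top_cm + 0.5,
                             aois$sheet$top_cm + aois$sheet$height_cm - 0.5)

  x <- rep(ev_x, block)
  y <- rep(ev_y, block)
  # transit samples interpolate between the previous and the next target
  if (any(n_sac > 0)) {
    ev_id <- rep(seq_len(keep_n), n_sac)
    frk <- unlist(lapply(n_sac, seq_len), use.names = FALSE) /
      (rep(n_sac, n_sac) + 1)
    sidx <- rep(ev_start, n_sac) +
      unlist(lapply(n_sac, seq_len), use.names = FALSE) - 1L
    x[sidx] <- ev_x[ev_id - 1L] + frk * (ev_x[ev_id] - ev_x[ev_id - 1L])
    y[sidx] <- ev_y[ev_id - 1L] + frk * (ev_y[ev_id] - ev_y[ev_id - 1L])
  }
  x <- x[seq_len(n_total)] + stats::rnorm(n_total, 0,
                                          params$fixation_jitter_cm)
  y <- y[seq_len(n_total)] + stats::rnorm(n_total, 0,
                                          params$fixation_jitter_cm)
  tgt_label <- ev_lab

  # --- pupil, head distance ---
  base_p <- params$pupil_base_mm[[tl]] + participant$pupil_offset_mm +
    stats::rnorm(1, 0, params$pupil_session_sd)
  ar <- as.numeric(stats::filter(
    stats::rnorm(n_total, 0,
                 params$pupil_ar_sd * sqrt(1 - params$pupil_ar1^2)),
    params$pupil_ar1, method = "recursive"))
  pupil <- base_p + ar
  pl <- pupil + params$pupil_eye_gap_mm / 2 +
    stats::rnorm(n_total, 0, params$pupil_meas_sd)
  pr <- pupil - params$pupil_eye_gap_mm / 2 +
    stats::rnorm(n_total, 0, params$pupil_meas_sd)
  head <- params$head_distance_cm + participant$head_offset_cm +
    stats::rnorm(n_total, 0, params$head_within_sd)

  left_valid <- rep(TRUE, n_total)
  right_valid <- rep(TRUE, n_total)

  # --- inject blinks (both-eye gaps inside the 100-600 ms band) ---
  minutes <- params$session_seconds / 60
  nb <- stats::rpois(1, blink_rate * minutes)
  onsets_ms <- numeric(0)
  durs_ms <- numeric(0)
  if (nb > 0) {
    cand <- sort(stats::runif(nb, 2, params$session_seconds - 2)) * 1000
    keep <- c(TRUE, diff(cand) > 1500)
    cand <- cand[keep]
    for (t0 in cand) {
      repeat {
        d <- stats::rnorm(1, params$blink_dur_mean_ms[[tl]],
                          params$blink_dur_sd_ms)
        if (d > 135 && d < 565) break
      }
      k_b <- min(16L, max(4L, as.integer(round(d / period))))
      i0 <- as.integer(round(t0 / period)) + 1L
      if (i0 + k_b - 1L > n_total) next
      ii <- i0:(i0 + k_b - 1L)
      left_valid[ii] <- FALSE
      right_valid[ii] <- FALSE
      onsets_ms <- c(onsets_ms, (i0 - 1L) * period)
      durs_ms <- c(durs_ms, k_b * period)
    }
  }

  # sporadic one-eye dropouts (position kept from the other eye)
  n_drop <- round(params$one_eye_invalid_rate * n_total)
  if (n_drop > 0) {
    ok <- which(left_valid & right_valid)
    drop <- sample(ok, min(n_drop, length(ok)))
    eye_left <- stats::runif(length(drop)) < 0.5
    left_valid[drop[eye_left]] <- FALSE
    right_valid[drop[!eye_left]] <- FALSE
  }

  both_invalid <- !left_valid & !right_valid
  x[both_invalid] <- NA_real_
  y[both_invalid] <- NA_real_
  pl[!left_valid] <- NA_real_
  pr[!right_valid] <- NA_real_

  samples <- data.frame(
    t_ms = (seq_len(n_total) - 1) * period,
    left_valid = left_valid, right_valid = right_valid,
    x_cm = x, y_cm = y,
    pupil_left_mm = pl, pupil_right_mm = pr,
    eye_distance_cm = head)
  out <- gaze_stream(samples, geometry, participant_id = participant_id,
                     condition_id = condition_id)
  attr(out, "ground_truth") <- list(
    n_blinks = length(onsets_ms), blink_onsets_ms = onsets_ms,
    blink_durations_ms = durs_ms, pupil_base_mm = base_p,
    target_labels = tgt_label)
  out
}

#' Simulate ISA ratings and NASA-TLX components for one session
#'
#' Subjective workload is a monotone noisy function of condition demand:
#' ratings rise with traffic and complexity, with participant-level offsets.
#'
#' @param cond A [condition()].
#' @param params A [cohort_params()].
#' @param participant List with `isa_offset`, `nasa_offset`.
#' @param seed RNG seed.
#' @return List with `isa_ratings` (8 integers in 1..7) and
#'   `nasa_components` (6 integers in 1..20).
#' @export
simulate_scores <- function(cond, params,
                            participant = list(isa_offset = 0,
                                               nasa_offset = 0),
                            seed = 1) {
  set.seed(seed)
  tl <- traffic_label(cond)
  ci <- match(cond$complexity, c("low", "medium", "high"))
  m_isa <- params$isa_cond_mean[tl, ci] + participant$isa_offset
  isa <- pmin(7L, pmax(1L, as.integer(round(
    stats::rnorm(8, m_isa, params$isa_rating_sd)))))
  m_comp <- (params$nasa_cond_mean[tl, ci] + participant$nasa_offset) / 6
  nasa <- pmin(20L, pmax(1L, as.integer(round(
    stats::rnorm(6, m_comp, params$nasa_component_sd)))))
  list(isa_ratings = isa, nasa_components = nasa)
}

#' Draw participant-level random effects and solver status
#'
#' @param params A [cohort_params()].
#' @param seed RNG seed.
#' @return Data.frame with one row per participant: pupil/blink/head/ISA/
#'   NASA effects and ground-truth solver flags for the two conflicts.
#' @export
draw_participants <- function(params, seed) {
  set.seed(seed)
  n <- params$n_participants
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    pupil_offset_mm = stats::rnorm(n, 0, params$pupil_between_sd),
    blink_rate_mult = exp(stats::rnorm(n, 0,
                                       params$blink_rate_participant_sd_log)),
    head_offset_cm = stats::rnorm(n, 0, params$head_participant_sd),
    isa_offset = stats::rnorm(n, 0, params$isa_participant_sd),
    nasa_offset = stats::rnorm(n, 0, params$nasa_participant_sd),
    solver_easy = stats::runif(n) < params$solver_p[["easy"]],
    solver_difficult = stats::runif(n) < params$solver_p[["difficult"]])
}

#' Simulate a complete synthetic study
#'
#' Generates the six scripted scenarios and, for every participant and
#' condition, a gaze stream, an intervention log (12-high only) and
#' subjective scores, with all randomness derived from one seed via fixed
#' per-session substreams. Ground-truth generative parameters are bundled
#' for recovery tests.
#'
#' @param params A [cohort_params()].
#' @param seed Integer seed.
#' @param keep_streams Keep the raw streams in the result (default TRUE;
#'   set to FALSE for large cohorts and analyze sessions on the fly with
#'   [analyze_cohort()]).
#' @return A list of class `synthetic_cohort`: `params`, `seed`,
#'   `scenarios` (by condition id), `participants` (ground-truth effects),
#'   `sessions` (list with `participant_id`, `condition_id`, `stream`,
#'   `interventions`, `scores`, `ground_truth`).
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1,
                            keep_streams = TRUE) {
  participants <- draw_participants(params, seed)
  grid <- condition_grid()
  scenarios <- lapply(seq_len(nrow(grid)), function(i)
    generate_scenario(condition(grid$traffic[i], grid$complexity[i])))
  names(scenarios) <- grid$id
  sessions <- vector("list", nrow(participants) * nrow(grid))
  k <- 0L
  for (p in seq_len(nrow(participants))) {
    pr <- as.list(participants[p, ])
    solver <- list(easy = pr$solver_easy, difficult = pr$solver_difficult)
    for (ci in seq_len(nrow(grid))) {
      k <- k + 1L
      sc <- scenarios[[ci]]
      s_seed <- session_seed(seed, p, ci)
      iv <- if (length(sc$conflicts) > 0)
        simulate_interventions(sc, solver, params, s_seed) else
          data.frame(t_s = numeric(0), flight = character(0),
                     kind = character(0), value = numeric(0))
      stream <- simulate_gaze(sc, params, participant = pr, solver = solver,
                              interventions = iv, seed = s_seed + 1L,
                              participant_id = pr$participant_id,
                              condition_id = grid$id[ci])
      scores <- simulate_scores(condition(grid$traffic[ci],
                                          grid$complexity[ci]),
                                params, participant = pr, seed = s_seed + 2L)
      gt <- attr(stream, "ground_truth")
      sessions[[k]] <- list(
        participant_id = pr$participant_id, condition_id = grid$id[ci],
        stream = if (keep_streams) stream else NULL,
        interventions = iv, scores = scores, ground_truth = gt)
    }
  }
  structure(list(params = params, seed = seed, scenarios = scenarios,
                 participants = participants, sessions = sessions),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants x %d conditions (seed %s)\n",
              nrow(x$participants), length(x$scenarios), x$seed))
  invisible(x)
}
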