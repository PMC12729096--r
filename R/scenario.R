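#' Aircraft trajectory in world units
#'
#' A trajectory is a sequence of waypoints in sector coordinates (nautical
#' miles, origin at the display centre, x east, y north) with altitude (ft)
#' and ground speed (kn). Between waypoints the aircraft moves with constant
#' velocity (piecewise-linear interpolation of position and altitude); beyond
#' the last waypoint it holds the final state.
#'
#' @param flight Flight label, e.g. `"HYG532"`.
#' @param waypoints Data.frame with columns `t_s`, `x_nm`, `y_nm`, `alt_ft`,
#'   `gs_kn`; `t_s` strictly increasing.
#' @param route_class `"standard"` or `"non-standard"`.
#' @param vertical_rate_ft_min Climb/descent rate used when an altitude
#'   clearance is applied (default 1500 ft/min).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(flight, waypoints, route_class = "standard",
                       vertical_rate_ft_min = 1500) {
  stopifnot(all(c("t_s", "x_nm", "y_nm", "alt_ft", "gs_kn") %in%
                  names(waypoints)))
  if (is.unsorted(waypoints$t_s, strictly = TRUE))
    stop("waypoint times must be strictly increasing", call. = FALSE)
  route_class <- match.arg(route_class, c("standard", "non-standard"))
  structure(list(flight = flight, waypoints = as.data.frame(waypoints),
                 route_class = route_class,
                 vertical_rate_ft_min = vertical_rate_ft_min),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %s (%s route), %d waypoints, %g-%g ft\n",
              x$flight, x$route_class, nrow(x$waypoints),
              min(x$waypoints$alt_ft), max(x$waypoints$alt_ft)))
  invisible(x)
}

#' Linear world-to-screen viewport
#'
#' Maps sector coordinates (NM, origin at display centre, y north) onto the
#' screen (cm, origin top-left, y down) with a single isotropic scale chosen
#' so that the sector's east-west extent fills the active-sector rectangle.
#'
#' @param geometry A [screen_geometry()].
#' @param sector_halfwidth_nm Half the east-west extent of the active sector
#'   in NM (default 30, i.e. the 27.5 cm sector rectangle spans 60 NM).
#' @return An object of class `viewport` with the scale in cm/NM.
#' @export
make_viewport <- function(geometry, sector_halfwidth_nm = 30) {
  sector_w_cm <- 27.5
  structure(list(geometry = geometry,
                 scale_cm_per_nm = sector_w_cm / (2 * sector_halfwidth_nm)),
            class = "viewport")
}

#' Project world positions to screen coordinates
#'
#' @param viewport A [make_viewport()].
#' @param x_nm,y_nm World coordinates (vectorised).
#' @return Data.frame with `x_cm`, `y_cm` (top-left origin, y down).
#' @export
project_to_screen <- function(viewport, x_nm, y_nm) {
  g <- viewport$geometry
  data.frame(x_cm = g$display_width_cm / 2 + x_nm * viewport$scale_cm_per_nm,
             y_cm = g$display_height_cm / 2 - y_nm * viewport$scale_cm_per_nm)
}

move_toward <- function(from, to, step) {
  # advance from -> to by at most step (>= 0)
  from + sign(to - from) * pmin(abs(to - from), step)
}

#' Aircraft states over time, with clearances applied
#'
#' Evaluates a trajectory at the requested times, after applying any
#' controller clearances from an intervention log. Altitude clearances take
#' effect at their issue time with the trajectory's climb/descent rate (not
#' instantaneously); speed clearances rescale progress along the route from
#' the issue time onward.
#'
#' @param traj A [trajectory()].
#' @param times_s Numeric vector of times (s since scenario onset).
#' @param interventions Optional data.frame with columns `t_s`, `flight`,
#'   `kind` (`"altitude"`, `"speed"`, `"accept"`), `value` (cleared level in
#'   ft or ground speed in kn). Only rows matching `traj$flight` apply;
#'   `accept` rows do not alter motion.
#' @return Data.frame `t_s`, `x_nm`, `y_nm`, `alt_ft`.
#' @export
traj_states <- function(traj, times_s, interventions = NULL) {
  wp <- traj$waypoints
  iv <- NULL
  if (!is.null(interventions) && nrow(interventions) > 0) {
    iv <- interventions[interventions$flight == traj$flight &
                          interventions$kind != "accept", , drop = FALSE]
    iv <- iv[order(iv$t_s), , drop = FALSE]
  }

  # --- horizontal motion: arc length along the waypoint polyline ---
  seg <- sqrt(diff(wp$x_nm)^2 + diff(wp$y_nm)^2)
  cd <- c(0, cumsum(seg))                      # cumulative distance (NM)
  s_base <- function(t) stats::approx(wp$t_s, cd, t, rule = 2)$y
  s <- s_base(times_s)
  if (!is.null(iv)) {
    sp <- iv[iv$kind == "speed", , drop = FALSE]
    if (nrow(sp) > 0) {
      # progress after each clearance is rescaled so ground speed equals the
      # cleared value; clearances compose in time order
      bounds <- c(sp$t_s, Inf)
      base_speed_at <- function(t) {           # NM/s just after t on base plan
        i <- findInterval(t, wp$t_s, rightmost.closed = TRUE)
        i <- pmin(pmax(i, 1), length(seg))
        seg[i] / diff(wp$t_s)[i]
      }
      factor_prev <- 1
      s_at_issue <- s_base(sp$t_s[1])
      s_mod_issue <- s_at_issue                # modified progress at issue time
      for (k in seq_len(nrow(sp))) {
        v_new <- sp$value[k] / 3600            # kn -> NM/s
        v_cur <- factor_prev * base_speed_at(sp$t_s[k])
        if (v_cur <= 0)
          stop("speed clearance on stationary segment for ", traj$flight,
               call. = FALSE)
        f <- factor_prev * (v_new / v_cur)
        lo <- sp$t_s[k]; hi <- bounds[k + 1]
        idx <- times_s >= lo & times_s < hi
        s[idx] <- s_mod_issue + f * (s_base(times_s[idx]) - s_base(lo))
        if (is.finite(hi))
          s_mod_issue <- s_mod_issue + f * (s_base(hi) - s_base(lo))
        factor_prev <- f
      }
      s <- pmin(s, max(cd))
    }
  }
  x <- stats::approx(cd, wp$x_nm, s, rule = 2, ties = "ordered")$y
  y <- stats::approx(cd, wp$y_nm, s, rule = 2, ties = "ordered")$y

  # --- vertical profile ---
  alt_base <- function(t) stats::approx(wp$t_s, wp$alt_ft, t, rule = 2)$y
  alt <- alt_base(times_s)
  if (!is.null(iv)) {
    av <- iv[iv$kind == "altitude", , drop = FALSE]
    if (nrow(av) > 0) {
      rate <- traj$vertical_rate_ft_min / 60   # ft/s
      alt_start <- numeric(nrow(av))
      for (k in seq_len(nrow(av))) {
        if (k == 1) {
          alt_start[k] <- alt_base(av$t_s[k])
        } else {
          ramp_done <- av$t_s[k - 1] +
            abs(av$value[k - 1] - alt_start[k - 1]) / rate
          if (av$t_s[k] < ramp_done)
            stop("overlapping altitude clearances for ", traj$flight,
                 " at t = ", av$t_s[k], " s", call. = FALSE)
          alt_start[k] <- av$value[k - 1]
        }
      }
      for (k in seq_len(nrow(av))) {
        idx <- times_s >= av$t_s[k]
        if (k < nrow(av)) idx <- idx & times_s < av$t_s[k + 1]
        alt[idx] <- move_toward(alt_start[k], av$value[k],
                                rate * (times_s[idx] - av$t_s[k]))
      }
    }
  }
  data.frame(t_s = times_s, x_nm = x, y_nm = y, alt_ft = alt)
}

#' Screen position of an aircraft over time
#'
#' @inheritParams traj_states
#' @param viewport A [make_viewport()].
#' @return Data.frame `t_s`, `x_cm`, `y_cm`.
#' @export
screen_position <- function(traj, times_s, viewport, interventions = NULL) {
  st <- traj_states(traj, times_s, interventions)
  cbind(t_s = st$t_s, project_to_screen(viewport, st$x_nm, st$y_nm))
}

#' Scripted conflict description
#'
#' @param name Conflict label (e.g. `"easy"`).
#' @param aircraft Character vector of 2 or 3 flight labels.
#' @param scripted_violation_s Time (s after scenario onset) at which the
#'   unresolved conflict first violates the separation minima.
#' @param window_s Length-2 numeric: the analysis window over which per
#'   aircraft fixation time and interventions are accumulated.
#' @return An object of class `conflict_spec`.
#' @export
conflict_spec <- function(name, aircraft, scripted_violation_s, window_s) {
  stopifnot(length(aircraft) %in% c(2, 3), length(window_s) == 2,
            window_s[1] < window_s[2])
  structure(list(name = name, aircraft = aircraft,
                 scripted_violation_s = scripted_violation_s,
                 window_s = window_s),
            class = "conflict_spec")
}

#' Experimental condition (traffic x complexity)
#'
#' @param traffic Number of simultaneous aircraft: 6 or 12.
#' @param complexity `"low"`, `"medium"` or `"high"`.
#' @return A list with `traffic`, `complexity` and an `id` like `"t12_high"`.
#' @export
condition <- function(traffic, complexity) {
  traffic <- as.integer(traffic)
  if (!traffic %in% c(6L, 12L)) stop("traffic must be 6 or 12", call. = FALSE)
  complexity <- match.arg(complexity, c("low", "medium", "high"))
  list(traffic = traffic, complexity = complexity,
       id = paste0("t", traffic, "_", complexity))
}

#' The six traffic x complexity conditions
#'
#' @return A data.frame with columns `traffic`, `complexity`, `id` (6 rows).
#' @export
condition_grid <- function() {
  g <- expand.grid(complexity = c("low", "medium", "high"),
                   traffic = c(6L, 12L), stringsAsFactors = FALSE)
  data.frame(traffic = g$traffic, complexity = g$complexity,
             id = paste0("t", g$traffic, "_", g$complexity))
}

#' First time an aircraft is inside the active sector
#'
#' Scans the scenario time grid for the first time the projected aircraft
#' symbol lies inside the active-sector rectangle. Used to clip cumulative
#' fixation time for aircraft that enter the sector after scenario onset.
#'
#' @param traj A [trajectory()].
#' @param scenario A scenario (for viewport, geometry and duration).
#' @param grid_s Scan step in seconds (default 1).
#' @return Entry time in s, or `NA` if the aircraft never enters.
#' @export
sector_entry_s <- function(traj, scenario, grid_s = 1) {
  times <- seq(0, scenario$duration_s, by = grid_s)
  pos <- screen_position(traj, times, scenario$viewport)
  aois <- build_static_aois(scenario$geometry)
  inside <- point_in_rect(pos$x_cm, pos$y_cm, aois$sector)
  if (!any(inside)) return(NA_real_)
  times[which(inside)[1]]
}
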