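#' Rectangular area of interest
#'
#' Screen rectangle in cm, top-left origin. Rectangles are closed on their
#' left and top edges and open on their right and bottom edges, which makes
#' boundary assignment deterministic.
#'
#' @param name Label.
#' @param left_cm,top_cm Top-left corner.
#' @param width_cm,height_cm Size (both > 0).
#' @return An object of class `rect_aoi`.
#' @export
rect_aoi <- function(name, left_cm, top_cm, width_cm, height_cm) {
  if (width_cm <= 0 || height_cm <= 0)
    stop("rect_aoi dimensions must be positive", call. = FALSE)
  structure(list(name = name, left_cm = left_cm, top_cm = top_cm,
                 width_cm = width_cm, height_cm = height_cm),
            class = "rect_aoi")
}

#' @export
print.rect_aoi <- function(x, ...) {
  cat(sprintf("<rect_aoi> %s: %.2f x %.2f cm at (%.2f, %.2f)\n",
              x$name, x$width_cm, x$height_cm, x$left_cm, x$top_cm))
  invisible(x)
}

#' Point-in-rectangle test (closed left/top, open right/bottom)
#'
#' @param x_cm,y_cm Point coordinates (vectorised).
#' @param rect A [rect_aoi()].
#' @return Logical vector.
#' @export
point_in_rect <- function(x_cm, y_cm, rect) {
  x_cm >= rect$left_cm & x_cm < rect$left_cm + rect$width_cm &
    y_cm >= rect$top_cm & y_cm < rect$top_cm + rect$height_cm
}

#' Static screen areas of interest
#'
#' Builds the three predefined static AOIs of the radar display: the active
#' sector (a centred 27.5 x 20.5 cm rectangle), the flight-plan sheet
#' (17 x 7.5 cm flush to the top-right corner), and the surrounding
#' out-of-sector airspace, represented as the complement of the other two
#' within the display. The sheet takes precedence over the sector where the
#' two rectangles touch, so the three effective regions are pairwise disjoint
#' and cover the display.
#'
#' @param geometry A [screen_geometry()].
#' @param sector_cm,sheet_cm Length-2 sizes in cm (width, height).
#' @return A list of class `static_aois` with elements `sector`, `sheet`
#'   ([rect_aoi()]s) and `display` (width/height in cm).
#' @export
build_static_aois <- function(geometry, sector_cm = c(27.5, 20.5),
                              sheet_cm = c(17, 7.5)) {
  W <- geometry$display_width_cm
  H <- geometry$display_height_cm
  if (W < sector_cm[1] || H < sector_cm[2] ||
      W < sheet_cm[1] || H < sheet_cm[2])
    stop("display too small for the configured AOIs", call. = FALSE)
  structure(
    list(sector = rect_aoi("sector", (W - sector_cm[1]) / 2,
                           (H - sector_cm[2]) / 2,
                           sector_cm[1], sector_cm[2]),
         sheet = rect_aoi("sheet", W - sheet_cm[1], 0,
                          sheet_cm[1], sheet_cm[2]),
         display = c(width_cm = W, height_cm = H)),
    class = "static_aois")
}

#' Assign fixations to static AOIs
#'
#' Labels each fixation centroid with the unique static region containing
#' it. Precedence is sheet > sector > out-of-sector (the sheet and sector
#' rectangles can share a boundary strip, and out-of-sector is the
#' complement). Centroids outside the display get `"off_display"`.
#'
#' @param fixations Data.frame with `centroid_x_cm`, `centroid_y_cm` (as
#'   returned by [detect_fixations()]), or a single fixation as a list.
#' @param aois A [build_static_aois()] result.
#' @return Character vector of labels: `"sheet"`, `"sector"`,
#'   `"out_of_sector"` or `"off_display"`.
#' @export
assign_fixation_static <- function(fixations, aois) {
  x <- fixations$centroid_x_cm
  y <- fixations$centroid_y_cm
  lab <- rep("out_of_sector", length(x))
  lab[point_in_rect(x, y, aois$sector)] <- "sector"
  lab[point_in_rect(x, y, aois$sheet)] <- "sheet"
  off <- x < 0 | x > aois$display[["width_cm"]] |
         y < 0 | y > aois$display[["height_cm"]] | is.na(x) | is.na(y)
  lab[off] <- "off_display"
  lab
}

#' Dynamic (aircraft-centred) AOI specification
#'
#' Every aircraft gets a moving rectangle of the same size, centred on its
#' projected symbol position and extended, if a tag offset is given, to also
#' cover the data-tag box (the AOI becomes the bounding box of the symbol
#' rectangle and the same rectangle displaced by the offset).
#'
#' @param width_cm,height_cm Rectangle size (defaults 3 x 2 cm, tag
#'   included).
#' @param tag_offset_cm Length-2 displacement of the data-tag box from the
#'   symbol (default `c(0, 0)`, i.e. the tag lies within the base rectangle).
#' @return An object of class `dynamic_aoi_spec`.
#' @export
dynamic_aoi_spec <- function(width_cm = 3, height_cm = 2,
                             tag_offset_cm = c(0, 0)) {
  if (width_cm <= 0 || height_cm <= 0)
    stop("dynamic AOI size must be positive", call. = FALSE)
  stopifnot(length(tag_offset_cm) == 2)
  structure(list(width_cm = width_cm, height_cm = height_cm,
                 tag_offset_cm = tag_offset_cm),
            class = "dynamic_aoi_spec")
}

#' Dynamic AOI of one aircraft at one time
#'
#' @param traj A [trajectory()].
#' @param t_ms Time in ms since scenario onset; must lie within the scenario.
#' @param spec A [dynamic_aoi_spec()].
#' @param scenario The scenario providing the viewport and duration.
#' @param interventions Optional intervention log applied to the trajectory.
#' @return A [rect_aoi()] centred on the aircraft (extended over the tag).
#' @export
dynamic_aoi_at <- function(traj, t_ms, spec, scenario, interventions = NULL) {
  t_s <- t_ms / 1000
  if (t_s < 0 || t_s > scenario$duration_s)
    stop("t_ms outside the scenario time span", call. = FALSE)
  pos <- screen_position(traj, t_s, scenario$viewport, interventions)
  left <- pos$x_cm - spec$width_cm / 2
  top <- pos$y_cm - spec$height_cm / 2
  w <- spec$width_cm
  h <- spec$height_cm
  off <- spec$tag_offset_cm
  if (any(off != 0)) {    # bounding box of symbol rect and tag rect
    left2 <- left + off[1]
    top2 <- top + off[2]
    l <- min(left, left2); tp <- min(top, top2)
    w <- max(left + w, left2 + w) - l
    h <- max(top + h, top2 + h) - tp
    left <- l; top <- tp
  }
  rect_aoi(traj$flight, left, top, w, h)
}

# Per-sample containment of points in each aircraft's dynamic AOI.
# Returns a logical matrix [time, aircraft].
dynamic_containment <- function(x_cm, y_cm, times_s, trajectories, spec,
                                viewport, interventions = NULL) {
  out <- matrix(FALSE, length(times_s), length(trajectories))
  colnames(out) <- vapply(trajectories, `[[`, "", "flight")
  half_w <- spec$width_cm / 2
  half_h <- spec$height_cm / 2
  off <- spec$tag_offset_cm
  for (j in seq_along(trajectories)) {
    pos <- screen_position(trajectories[[j]], times_s, viewport, interventions)
    left <- pos$x_cm - half_w
    top <- pos$y_cm - half_h
    right <- pos$x_cm + half_w
    bottom <- pos$y_cm + half_h
    if (any(off != 0)) {
      left <- pmin(left, left + off[1]); right <- pmax(right, right + off[1])
      top <- pmin(top, top + off[2]); bottom <- pmax(bottom, bottom + off[2])
    }
    out[, j] <- x_cm >= left & x_cm < right & y_cm >= top & y_cm < bottom
  }
  out
}

#' Assign fixations to aircraft via dynamic AOIs
#'
#' Each fixation is assigned to the aircraft whose dynamic AOI contains the
#' fixation centroid for the greatest fraction of the fixation's duration,
#' evaluated on the sample grid; `NA` if no AOI ever contains it. Ties are
#' broken by the AOI centre nearest to the centroid at the fixation
#' midpoint.
#'
#' @param fixations Data.frame from [detect_fixations()].
#' @param trajectories List of [trajectory()] objects.
#' @param spec A [dynamic_aoi_spec()].
#' @param scenario The scenario providing the viewport and sample period.
#' @param interventions Optional intervention log.
#' @return Character vector of flight labels (or `NA`) per fixation.
#' @export
assign_fixation_dynamic <- function(fixations, trajectories, spec, scenario,
                                    interventions = NULL) {
  n <- nrow(fixations)
  if (n == 0 || length(trajectories) == 0) return(rep(NA_character_, n))
  period_ms <- sample_period_ms(scenario$geometry)
  labels <- vapply(trajectories, `[[`, "", "flight")
  # aircraft AOI bounds precomputed once on the sample grid spanning the
  # fixations, then indexed per fixation
  t0 <- min(fixations$start_ms)
  grid_ms <- seq(t0, max(fixations$end_ms), by = period_ms)
  nt <- length(grid_ms)
  half_w <- spec$width_cm / 2
  half_h <- spec$height_cm / 2
  off <- spec$tag_offset_cm
  L <- R <- Tt <- B <- matrix(NA_real_, nt, length(labels))
  cx <- cy <- matrix(NA_real_, nt, length(labels))
  for (j in seq_along(trajectories)) {
    pos <- screen_position(trajectories[[j]], grid_ms / 1000,
                           scenario$viewport, interventions)
    cx[, j] <- pos$x_cm
    cy[, j] <- pos$y_cm
    L[, j] <- pos$x_cm - half_w
    R[, j] <- pos$x_cm + half_w
    Tt[, j] <- pos$y_cm - half_h
    B[, j] <- pos$y_cm + half_h
    if (any(off != 0)) {
      L[, j] <- pmin(L[, j], L[, j] + off[1])
      R[, j] <- pmax(R[, j], R[, j] + off[1])
      Tt[, j] <- pmin(Tt[, j], Tt[, j] + off[2])
      B[, j] <- pmax(B[, j], B[, j] + off[2])
    }
  }
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    i0 <- round((fixations$start_ms[i] - t0) / period_ms) + 1L
    i1 <- min(nt, round((fixations$end_ms[i] - t0) / period_ms))
    rows <- i0:max(i0, i1)
    px <- fixations$centroid_x_cm[i]
    py <- fixations$centroid_y_cm[i]
    cont <- px >= L[rows, , drop = FALSE] & px < R[rows, , drop = FALSE] &
      py >= Tt[rows, , drop = FALSE] & py < B[rows, , drop = FALSE]
    frac <- colMeans(cont)
    if (all(frac == 0)) next
    best <- which(frac == max(frac))
    if (length(best) > 1) {
      mid_row <- rows[ceiling(length(rows) / 2)]
      d <- (cx[mid_row, best] - px)^2 + (cy[mid_row, best] - py)^2
      best <- best[which.min(d)]
    }
    out[i] <- labels[best]
  }
  out
}

#' Cumulative fixation time on one aircraft within a window
#'
#' Sums, over the fixations assigned to the aircraft, their overlap with the
#' window `[t0, t1]`, in seconds. For aircraft that enter the active sector
#' after `t0`, pass the entry time as `sector_entry_s` to clip the window
#' start (accumulation "starting from sector entry").
#'
#' @param fixations Data.frame with `start_ms`, `end_ms` and an `aircraft`
#'   column (from [assign_fixation_dynamic()]).
#' @param aircraft Flight label.
#' @param window_s Length-2 numeric window in seconds.
#' @param sector_entry_s Optional sector-entry time (s) clipping the window.
#' @return Seconds of assigned fixation time within the (clipped) window.
#' @export
cumulative_fixation_time <- function(fixations, aircraft, window_s,
                                     sector_entry_s = NULL) {
  stopifnot(length(window_s) == 2, window_s[1] < window_s[2])
  t0 <- window_s[1] * 1000
  t1 <- window_s[2] * 1000
  if (!is.null(sector_entry_s) && !is.na(sector_entry_s))
    t0 <- max(t0, sector_entry_s * 1000)
  f <- fixations[!is.na(fixations$aircraft) &
                   fixations$aircraft == aircraft, , drop = FALSE]
  if (nrow(f) == 0) return(0)
  sum(pmax(0, pmin(f$end_ms, t1) - pmax(f$start_ms, t0))) / 1000
}

#' Sliding-window attention share per aircraft
#'
#' For every grid time t (one sample period step, trailing window), computes
#' the percentage of the preceding `window_ms` spent fixating each
#' aircraft's dynamic AOI, plus the sum over aircraft (`total`).
#'
#' @param fixations Data.frame with `start_ms`, `end_ms`, `aircraft`.
#' @param aircraft Character vector of flight labels to report.
#' @param t_end_ms End of the record in ms.
#' @param window_ms Window length (default 10,000 ms).
#' @param step_ms Grid step (default one 30 Hz sample period).
#' @return Data.frame of class `attention_series`: `t_ms`, one column per
#'   aircraft, and `total`, shares in percent.
#' @export
sliding_window_attention <- function(fixations, aircraft, t_end_ms,
                                     window_ms = 10000,
                                     step_ms = 1000 / 30) {
  if (t_end_ms <= window_ms)
    stop("record shorter than the sliding window; use a shorter window",
         call. = FALSE)
  grid <- seq(window_ms, t_end_ms, by = step_ms)
  out <- data.frame(t_ms = grid)
  coverage_at <- function(st, en) {
    # piecewise-linear cumulative assigned time, queried at grid and grid - w
    if (length(st) == 0) return(numeric(length(grid)))
    knots <- sort(unique(c(0, st, en, t_end_ms)))
    cum <- vapply(knots, function(t)
      sum(pmax(0, pmin(en, t) - st)), numeric(1))
    f <- stats::approxfun(knots, cum, rule = 2)
    f(grid) - f(grid - window_ms)
  }
  for (a in aircraft) {
    f <- fixations[!is.na(fixations$aircraft) & fixations$aircraft == a, ,
                   drop = FALSE]
    out[[a]] <- 100 * coverage_at(f$start_ms, f$end_ms) / window_ms
  }
  out$total <- rowSums(out[, aircraft, drop = FALSE])
  class(out) <- c("attention_series", "data.frame")
  out
}
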