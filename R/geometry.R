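#' Screen geometry of the recording setup
#'
#' Describes the radar display and viewing conditions under which gaze was
#' recorded: physical display size, eye-to-screen distance and eye-tracker
#' sampling rate. All screen coordinates in the package are centimetres with
#' origin at the display's top-left corner, x rightwards, y downwards.
#'
#' @param display_width_cm,display_height_cm Physical display size in cm.
#'   Defaults match a 61 x 34 cm radar display.
#' @param viewing_distance_cm Eye-to-screen distance in cm (default 60).
#'   Values outside the plausible 30--120 cm band raise a warning.
#' @param sampling_rate_hz Eye-tracker sampling rate in Hz (default 30).
#' @param resolution_px Optional integer pair `c(width, height)` in pixels,
#'   used only to convert pixel input columns to cm at read time.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' sample_period_ms(geom)
#' @export
screen_geometry <- function(display_width_cm = 61,
                            display_height_cm = 34,
                            viewing_distance_cm = 60,
                            sampling_rate_hz = 30,
                            resolution_px = NULL) {
  stopifnot(is.numeric(display_width_cm), length(display_width_cm) == 1,
            is.numeric(display_height_cm), length(display_height_cm) == 1,
            is.numeric(viewing_distance_cm), length(viewing_distance_cm) == 1,
            is.numeric(sampling_rate_hz), length(sampling_rate_hz) == 1)
  if (display_width_cm <= 0 || display_height_cm <= 0)
    stop("display dimensions must be positive", call. = FALSE)
  if (viewing_distance_cm <= 0)
    stop("viewing_distance_cm must be positive", call. = FALSE)
  if (sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive", call. = FALSE)
  if (viewing_distance_cm < 30 || viewing_distance_cm > 120)
    warning("viewing_distance_cm = ", viewing_distance_cm,
            " cm is outside the plausible 30-120 cm band", call. = FALSE)
  if (!is.null(resolution_px)) {
    stopifnot(is.numeric(resolution_px), length(resolution_px) == 2,
              all(resolution_px > 0))
    resolution_px <- as.integer(resolution_px)
  }
  structure(
    list(display_width_cm = display_width_cm,
         display_height_cm = display_height_cm,
         viewing_distance_cm = viewing_distance_cm,
         sampling_rate_hz = sampling_rate_hz,
         resolution_px = resolution_px),
    class = "screen_geometry")
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %g x %g cm display, %g cm viewing distance, %g Hz\n",
              x$display_width_cm, x$display_height_cm,
              x$viewing_distance_cm, x$sampling_rate_hz))
  invisible(x)
}

#' Nominal sample period in milliseconds
#'
#' @param geometry A [screen_geometry()].
#' @return `1000 / sampling_rate_hz`, in ms.
#' @export
sample_period_ms <- function(geometry) {
  1000 / geometry$sampling_rate_hz
}

#' Convert an on-screen extent to visual angle
#'
#' Angular subtense of an extent seen frontally at a given distance:
#' `theta = 2 * atan(extent / (2 * distance))`, returned in degrees. The
#' central 27.5 x 20.5 cm sector of the display subtends 25.81 x 19.39 degrees
#' at the 60 cm viewing distance used throughout.
#'
#' @param extent_cm Extent on the screen in cm (>= 0). Vectorised.
#' @param distance_cm Viewing distance in cm (> 0).
#' @return Visual angle in degrees.
#' @seealso [visual_angle_to_cm()] for the inverse.
#' @examples
#' cm_to_visual_angle(27.5, 60) # 25.81
#' cm_to_visual_angle(20.5, 60) # 19.39
#' @export
cm_to_visual_angle <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive", call. = FALSE)
  if (any(extent_cm < 0)) stop("extent_cm must be non-negative", call. = FALSE)
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Convert a visual angle to an on-screen extent
#'
#' Inverse of [cm_to_visual_angle()]: `extent = 2 * distance * tan(angle/2)`.
#' Used to express the 1 degree fixation dispersion bound in screen cm.
#'
#' @param angle_deg Visual angle in degrees (must be < 180). Vectorised.
#' @param distance_cm Viewing distance in cm (> 0).
#' @return Extent in cm.
#' @examples
#' visual_angle_to_cm(1, 60) # about 1.047 cm
#' @export
visual_angle_to_cm <- function(angle_deg, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance_cm must be positive", call. = FALSE)
  if (any(angle_deg >= 180)) stop("angle_deg must be below 180", call. = FALSE)
  2 * distance_cm * tan(angle_deg * pi / 360)
}
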