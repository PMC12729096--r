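#' Detection parameters for ocular events
#'
#' Thresholds for blink and fixation detection. Blinks are simultaneous
#' both-eye data loss lasting 100--600 ms (inclusive band); a fixation is any
#' gaze remaining within 1 degree of visual angle for at least 100 ms.
#'
#' @param blink_min_ms,blink_max_ms Blink duration band in ms (defaults 100,
#'   600; both ends inclusive).
#' @param fixation_dispersion_deg Fixation dispersion bound in degrees of
#'   visual angle (default 1). Interpreted as the maximum pairwise distance
#'   between any two samples of the fixation (a containment bound).
#' @param fixation_min_ms Minimum fixation duration in ms (default 100).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(blink_min_ms = 100, blink_max_ms = 600,
                             fixation_dispersion_deg = 1,
                             fixation_min_ms = 100) {
  if (!(blink_min_ms > 0 && blink_min_ms < blink_max_ms))
    stop("need 0 < blink_min_ms < blink_max_ms", call. = FALSE)
  if (fixation_dispersion_deg <= 0)
    stop("fixation_dispersion_deg must be positive", call. = FALSE)
  if (fixation_min_ms <= 0)
    stop("fixation_min_ms must be positive", call. = FALSE)
  structure(list(blink_min_ms = blink_min_ms, blink_max_ms = blink_max_ms,
                 fixation_dispersion_deg = fixation_dispersion_deg,
                 fixation_min_ms = fixation_min_ms),
            class = "detection_params")
}

empty_events <- function(cols) {
  as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Detect blinks as both-eye data-loss runs
#'
#' A blink is a maximal run of consecutive samples in which both eyes are
#' invalid, whose duration (run length times the sample period) lies within
#' the closed band `[blink_min_ms, blink_max_ms]`. Runs outside the band are
#' not blinks; they are returned separately as track-loss segments.
#'
#' @param stream A [gaze_stream()].
#' @param params A [detection_params()].
#' @return A list of class `blink_detection` with data.frames `blinks` and
#'   `track_loss`, each with columns `start_ms`, `end_ms`, `duration_ms`,
#'   `n_samples`. `end_ms` is exclusive (`start_ms + n_samples * period`).
#' @export
detect_blinks <- function(stream, params = detection_params()) {
  s <- stream$samples
  period <- sample_period_ms(stream$geometry)
  cols <- c("start_ms", "end_ms", "duration_ms", "n_samples")
  if (nrow(s) == 0) {
    out <- list(blinks = empty_events(cols), track_loss = empty_events(cols))
    class(out) <- "blink_detection"
    return(out)
  }
  if (is.unsorted(s$t_ms, strictly = TRUE))
    stop("gaze stream is not strictly time-ordered", call. = FALSE)
  invalid <- !s$left_valid & !s$right_valid
  r <- rle(invalid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  run_start <- starts[r$values]
  run_len <- r$lengths[r$values]
  dur <- run_len * period
  df <- data.frame(start_ms = s$t_ms[run_start],
                   end_ms = s$t_ms[run_start] + run_len * period,
                   duration_ms = dur,
                   n_samples = run_len)
  in_band <- dur >= params$blink_min_ms - 1e-9 &
             dur <= params$blink_max_ms + 1e-9
  out <- list(blinks = df[in_band, , drop = FALSE],
              track_loss = df[!in_band, , drop = FALSE])
  rownames(out$blinks) <- rownames(out$track_loss) <- NULL
  class(out) <- "blink_detection"
  out
}

#' @export
print.blink_detection <- function(x, ...) {
  cat(sprintf("<blink_detection> %d blink(s), %d track-loss segment(s)\n",
              nrow(x$blinks), nrow(x$track_loss)))
  invisible(x)
}

#' Detect fixations with a dispersion-threshold (I-DT) algorithm
#'
#' Grows windows of consecutive position-valid samples while the maximum
#' pairwise Euclidean distance between member samples stays within the
#' dispersion bound (1 degree by default, converted to screen cm at the
#' viewing distance); when growth stops, the window is a fixation if its
#' duration reaches `fixation_min_ms`. Any sample without a usable position
#' (both eyes invalid) terminates the current window; no interpolation across
#' dropouts is performed. The centroid is the arithmetic mean of the member
#' positions. A window of n samples has duration `n * sample period`.
#'
#' @param stream A [gaze_stream()].
#' @param params A [detection_params()].
#' @param geometry Screen geometry providing the viewing distance; defaults
#'   to the stream's own geometry.
#' @return A data.frame of fixations: `start_ms`, `end_ms` (exclusive),
#'   `duration_ms`, `centroid_x_cm`, `centroid_y_cm`, `n_samples`.
#' @export
detect_fixations <- function(stream, params = detection_params(),
                             geometry = stream$geometry) {
  s <- stream$samples
  cols <- c("start_ms", "end_ms", "duration_ms",
            "centroid_x_cm", "centroid_y_cm", "n_samples")
  if (nrow(s) == 0) return(empty_events(cols))
  if (is.unsorted(s$t_ms, strictly = TRUE))
    stop("gaze stream is not strictly time-ordered", call. = FALSE)
  period <- sample_period_ms(geometry)
  disp_cm <- visual_angle_to_cm(params$fixation_dispersion_deg,
                                geometry$viewing_distance_cm)
  valid <- !is.na(s$x_cm) & !is.na(s$y_cm)
  win <- idt_windows_cpp(s$t_ms, ifelse(valid, s$x_cm, 0),
                         ifelse(valid, s$y_cm, 0), valid,
                         disp_cm, params$fixation_min_ms, period)
  if (nrow(win) == 0) return(empty_events(cols))
  fix <- data.frame(
    start_ms = s$t_ms[win$start],
    end_ms = s$t_ms[win$end] + period,
    duration_ms = s$t_ms[win$end] - s$t_ms[win$start] + period,
    centroid_x_cm = vapply(seq_len(nrow(win)), function(i)
      mean(s$x_cm[win$start[i]:win$end[i]]), numeric(1)),
    centroid_y_cm = vapply(seq_len(nrow(win)), function(i)
      mean(s$y_cm[win$start[i]:win$end[i]]), numeric(1)),
    n_samples = win$end - win$start + 1L)
  fix
}

#' Mean pupil diameter of a stream
#'
#' Per-sample pupil diameter is the mean of the available eyes (a single
#' valid eye suffices); the session index is the mean over all such samples.
#'
#' @param stream A [gaze_stream()].
#' @return Mean pupil diameter in mm; `NA` with a warning when no sample has
#'   a valid pupil reading.
#' @export
pupil_mean <- function(stream) {
  s <- stream$samples
  per_sample <- rowMeans(cbind(s$pupil_left_mm, s$pupil_right_mm),
                         na.rm = TRUE)
  per_sample <- per_sample[is.finite(per_sample)]
  if (length(per_sample) == 0) {
    warning("no valid pupil samples; returning NA", call. = FALSE)
    return(NA_real_)
  }
  mean(per_sample)
}

#' Blink count and mean duration
#'
#' @param blinks A data.frame of blinks (e.g. `detect_blinks(...)$blinks`) or
#'   a `blink_detection` object.
#' @return A list with `count` and `mean_duration_ms` (`NA` when there are no
#'   blinks).
#' @export
blink_stats <- function(blinks) {
  if (inherits(blinks, "blink_detection")) blinks <- blinks$blinks
  n <- nrow(blinks)
  list(count = n,
       mean_duration_ms = if (n > 0) mean(blinks$duration_ms) else NA_real_)
}
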