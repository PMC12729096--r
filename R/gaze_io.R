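#' Gaze-sample streams
#'
#' A gaze stream is the raw 30 Hz eye-tracker record for one participant in
#' one scenario: a time-ordered table of samples with per-eye validity flags,
#' a unified screen position in cm (top-left origin), per-eye pupil diameters
#' in mm, and optionally the eye-to-screen distance in cm. Timestamps are
#' milliseconds since scenario onset. When both eyes are invalid the position
#' and pupil fields are `NA`.
#'
#' @param samples A data.frame with columns `t_ms`, `left_valid`,
#'   `right_valid`, `x_cm`, `y_cm`, `pupil_left_mm`, `pupil_right_mm` and
#'   optionally `eye_distance_cm`.
#' @param geometry A [screen_geometry()].
#' @param participant_id,condition_id Optional labels carried along.
#'
#' @return An object of class `gaze_stream`: a list with elements `samples`,
#'   `geometry`, `participant_id`, `condition_id`.
#' @export
gaze_stream <- function(samples, geometry,
                        participant_id = NA_character_,
                        condition_id = NA_character_) {
  required <- c("t_ms", "left_valid", "right_valid", "x_cm", "y_cm",
                "pupil_left_mm", "pupil_right_mm")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols) > 0)
    stop("gaze samples missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  samples <- as.data.frame(samples)
  samples$left_valid <- as.logical(samples$left_valid)
  samples$right_valid <- as.logical(samples$right_valid)
  if (nrow(samples) > 1) {
    dt <- diff(samples$t_ms)
    bad <- which(dt <= 0)
    if (length(bad) > 0)
      stop("non-monotonic timestamps: row ", bad[1] + 1,
           " (t_ms = ", samples$t_ms[bad[1] + 1], ")", call. = FALSE)
    med <- stats::median(dt)
    nominal <- sample_period_ms(geometry)
    if (abs(med - nominal) > 0.1 * nominal)
      warning(sprintf(paste0("median inter-sample interval %.2f ms deviates ",
                             "more than 10%% from nominal %.2f ms"),
                      med, nominal), call. = FALSE)
  }
  # both-eye-invalid samples carry no position or pupil data
  both_invalid <- !samples$left_valid & !samples$right_valid
  samples$x_cm[both_invalid] <- NA_real_
  samples$y_cm[both_invalid] <- NA_real_
  samples$pupil_left_mm[!samples$left_valid] <- NA_real_
  samples$pupil_right_mm[!samples$right_valid] <- NA_real_
  structure(
    list(samples = samples, geometry = geometry,
         participant_id = participant_id, condition_id = condition_id),
    class = "gaze_stream")
}

#' @export
print.gaze_stream <- function(x, ...) {
  n <- nrow(x$samples)
  dur <- if (n > 0) (x$samples$t_ms[n] - x$samples$t_ms[1] +
                       sample_period_ms(x$geometry)) / 1000 else 0
  cat(sprintf("<gaze_stream> %d samples (%.1f s at %g Hz)", n, dur,
              x$geometry$sampling_rate_hz))
  if (!is.na(x$participant_id))
    cat(sprintf(" participant %s", x$participant_id))
  if (!is.na(x$condition_id))
    cat(sprintf(" condition %s", x$condition_id))
  cat("\n")
  invisible(x)
}

#' Read a gaze-sample file
#'
#' Reads a delimited-text gaze export (tab- or comma-separated, auto-detected,
#' one header row) into a [gaze_stream()]. Mandatory columns: `t_ms`,
#' `left_valid`, `right_valid`, `x_cm`, `y_cm`, `pupil_left_mm`,
#' `pupil_right_mm`; optional `eye_distance_cm`. Validity flags may be
#' logical, 0/1, or "true"/"false" strings. If positions are supplied as
#' pixels (`x_px`, `y_px`) instead of cm, `geometry$resolution_px` must be set
#' and the conversion is applied once at read time. Rows whose timestamp does
#' not parse as a number are rejected with a warning; non-monotonic
#' timestamps are an error naming the first offending row.
#'
#' @param path Path to the file.
#' @param geometry A [screen_geometry()].
#' @param participant_id,condition_id Optional labels.
#' @return A [gaze_stream()].
#' @export
read_gaze_samples <- function(path, geometry,
                              participant_id = NA_character_,
                              condition_id = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, na.strings = c("NA", ""), data.table = FALSE)
  if (!"x_cm" %in% names(raw) && all(c("x_px", "y_px") %in% names(raw))) {
    if (is.null(geometry$resolution_px))
      stop("pixel coordinates supplied but geometry$resolution_px is not set",
           call. = FALSE)
    raw$x_cm <- raw$x_px * geometry$display_width_cm / geometry$resolution_px[1]
    raw$y_cm <- raw$y_px * geometry$display_height_cm / geometry$resolution_px[2]
  }
  required <- c("t_ms", "left_valid", "right_valid", "x_cm", "y_cm",
                "pupil_left_mm", "pupil_right_mm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("gaze file ", path, " missing mandatory columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  t_num <- suppressWarnings(as.numeric(raw$t_ms))
  bad_t <- is.na(t_num)
  if (any(bad_t)) {
    warning("rejected ", sum(bad_t), " row(s) with unparsable timestamps",
            call. = FALSE)
    raw <- raw[!bad_t, , drop = FALSE]
    t_num <- t_num[!bad_t]
  }
  raw$t_ms <- t_num
  raw$left_valid <- normalize_flag(raw$left_valid)
  raw$right_valid <- normalize_flag(raw$right_valid)
  for (col in c("x_cm", "y_cm", "pupil_left_mm", "pupil_right_mm",
                "eye_distance_cm")) {
    if (col %in% names(raw)) raw[[col]] <- as.numeric(raw[[col]])
  }
  keep <- intersect(c(required, "eye_distance_cm"), names(raw))
  gaze_stream(raw[, keep, drop = FALSE], geometry,
              participant_id = participant_id, condition_id = condition_id)
}

normalize_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  if (anyNA(out))
    stop("unrecognized validity flag value: ",
         x[which(is.na(out))[1]], call. = FALSE)
  out
}

#' Write a gaze stream to a tab-separated file
#'
#' Inverse of [read_gaze_samples()]; the round trip is lossless for all
#' sample fields.
#'
#' @param stream A [gaze_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gaze_samples <- function(stream, path) {
  data.table::fwrite(stream$samples, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
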