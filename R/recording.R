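#' Sensor metadata for an IMU recording
#'
#' @param subject_id Non-empty subject identifier.
#' @param sensor_location One of `"ankle"` or `"proximal_shank"`.
#' @param sampling_rate_hz Sampling rate in Hz (> 0).
#' @param side Sensor side: `"left"`, `"right"` or `"unknown"`.
#'
#' @return An object of class `recording_meta`.
#' @export
recording_meta <- function(subject_id,
                           sensor_location = c("ankle", "proximal_shank"),
                           sampling_rate_hz = 100,
                           side = c("unknown", "left", "right")) {
  sensor_location <- match.arg(sensor_location)
  side <- match.arg(side)
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      !nzchar(subject_id)) {
    stop("`subject_id` must be a non-empty string", call. = FALSE)
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a positive number", call. = FALSE)
  }
  structure(
    list(subject_id = subject_id, sensor_location = sensor_location,
         sampling_rate_hz = as.numeric(sampling_rate_hz), side = side),
    class = "recording_meta"
  )
}

#' Tri-axial accelerometer + gyroscope recording
#'
#' The canonical in-memory container for a shank IMU recording. Acceleration
#' is stored in m/s^2 and angular velocity in deg/s. In the `"shank"` frame
#' the axis order is x = anteroposterior, y = mediolateral, z = vertical with
#' gravity along +z.
#'
#' @param time_s Monotone increasing time vector (seconds).
#' @param accel N x 3 acceleration matrix (m/s^2).
#' @param gyro N x 3 angular-velocity matrix (deg/s).
#' @param meta A [recording_meta()] object.
#' @param frame `"raw"` (as recorded) or `"shank"` (calibrated).
#'
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(time_s, accel, gyro, meta, frame = c("raw", "shank")) {
  frame <- match.arg(frame)
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  n <- length(time_s)
  if (nrow(accel) != n || nrow(gyro) != n) {
    stop("accel and gyro must have one row per time sample", call. = FALSE)
  }
  if (ncol(accel) != 3L || ncol(gyro) != 3L) {
    stop("accel and gyro must have exactly 3 columns", call. = FALSE)
  }
  if (n > 1L && any(diff(time_s) <= 0)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (!inherits(meta, "recording_meta")) {
    stop("`meta` must be a recording_meta object", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(time_s)
    expected <- 1 / meta$sampling_rate_hz
    if (any(abs(dt - expected) > 0.01 * expected + 1e-9)) {
      warning("time steps deviate from 1/sampling_rate by more than 1%")
    }
  }
  colnames(accel) <- c("ax", "ay", "az")
  colnames(gyro) <- c("gx", "gy", "gz")
  structure(
    list(time_s = as.numeric(time_s), accel = accel, gyro = gyro,
         meta = meta, frame = frame),
    class = "imu_recording"
  )
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$time_s)
  cat(sprintf(
    "<imu_recording> %d samples @ %g Hz (%.1f s), frame=%s, subject=%s\n",
    n, x$meta$sampling_rate_hz, n / x$meta$sampling_rate_hz, x$frame,
    x$meta$subject_id))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording` or `labeled_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) {
  if (inherits(rec, "labeled_recording")) rec <- rec$recording
  length(rec$time_s)
}

#' The seven harmonized activity classes (plus "unlabeled")
#' @export
ACTIVITY_CLASSES <- c("static", "walking", "running", "cycling",
                      "stair_ascent", "stair_descent", "other")

#' Labeled IMU recording
#'
#' An [imu_recording()] with one activity label per sample. Labels are drawn
#' from the seven harmonized classes ([ACTIVITY_CLASSES]) plus `"unlabeled"`;
#' raw dataset labels (e.g. PAMAP2 activity IDs as strings) are also accepted
#' before harmonization.
#'
#' @param recording An [imu_recording()].
#' @param labels Character vector, one label per sample.
#'
#' @return An object of class `labeled_recording`.
#' @export
labeled_recording <- function(recording, labels) {
  if (!inherits(recording, "imu_recording")) {
    stop("`recording` must be an imu_recording", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != length(recording$time_s)) {
    stop("labels must have one entry per sample", call. = FALSE)
  }
  structure(list(recording = recording, labels = labels),
            class = "labeled_recording")
}

#' @export
print.labeled_recording <- function(x, ...) {
  print(x$recording)
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-sample Boolean walking mask
#'
#' @param is_walking Logical vector, one value per sample of the source
#'   recording.
#' @param sampling_rate_hz Sampling rate of the source recording.
#' @param provenance Which detector produced the mask: `"freq"` (harmonic
#'   heuristic), `"ml_model"` (classifier), or `"truth"` (ground truth).
#'
#' @return An object of class `gait_mask`.
#' @export
gait_mask <- function(is_walking, sampling_rate_hz,
                      provenance = c("freq", "ml_model", "truth")) {
  provenance <- match.arg(provenance)
  structure(
    list(is_walking = as.logical(is_walking),
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         provenance = provenance),
    class = "gait_mask"
  )
}

#' @export
print.gait_mask <- function(x, ...) {
  n <- length(x$is_walking)
  cat(sprintf("<gait_mask> %d samples @ %g Hz, %.1f%% walking (%s)\n",
              n, x$sampling_rate_hz, 100 * mean(x$is_walking), x$provenance))
  invisible(x)
}

norm3 <- function(m) sqrt(rowSums(m^2))
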