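# PAMAP2 protocol-file layout (1-based column indices).
# 54 space-separated columns: 1 timestamp (s), 2 activity ID, 3 heart rate,
# then three 17-column IMU blocks (hand 4-20, chest 21-37, ankle 38-54).
# Within a block: 1 temperature, 2-4 accel +/-16 g (m/s^2), 5-7 accel +/-6 g,
# 8-10 gyro (rad/s), 11-13 magnetometer, 14-17 orientation (invalid).
PAMAP2_N_COLS <- 54L
PAMAP2_ANKLE_ACC16 <- 39:41
PAMAP2_ANKLE_GYRO <- 45:47
PAMAP2_VALID_IDS <- c(0L, 1:7, 9:13, 16:20, 24L)

#' Read a PAMAP2 protocol .dat file (ankle IMU)
#'
#' Parses the space-separated PAMAP2 protocol format and extracts the ankle
#' IMU channels: the wide-range (+/-16 g) accelerometer, already in m/s^2,
#' and the gyroscope, converted from rad/s to deg/s. Raw PAMAP2 activity IDs
#' are attached as string labels (harmonize with [harmonize_labels()]).
#'
#' Wireless dropouts appear as NaN runs: gaps up to `max_gap_s` are filled by
#' linear interpolation; longer gaps split the recording into contiguous
#' segments, returned as separate elements.
#'
#' @param path Path to a `subjectNNN.dat` protocol file.
#' @param subject_id Subject identifier stored in the metadata.
#' @param max_gap_s Longest NaN gap (seconds) bridged by interpolation.
#' @return A list of [labeled_recording()] segments (length 1 when no long
#'   gaps are present).
#' @export
read_pamap2 <- function(path, subject_id, max_gap_s = 0.2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, sep = "",
                           na.strings = c("NaN", "NA"),
                           colClasses = "numeric")
  if (ncol(raw) != PAMAP2_N_COLS) {
    stop(sprintf("malformed PAMAP2 file: expected %d columns, found %d",
                 PAMAP2_N_COLS, ncol(raw)), call. = FALSE)
  }
  ids <- as.integer(raw[[2]])
  bad <- setdiff(unique(ids), PAMAP2_VALID_IDS)
  if (length(bad) > 0) {
    stop("unknown PAMAP2 activity ID(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  time_s <- raw[[1]]
  accel <- as.matrix(raw[, PAMAP2_ANKLE_ACC16])
  gyro <- as.matrix(raw[, PAMAP2_ANKLE_GYRO]) * 180 / pi
  rate <- 100
  max_gap <- max(1L, as.integer(round(max_gap_s * rate)))

  # rows where any used channel is missing
  miss <- rowSums(is.na(cbind(accel, gyro))) > 0
  segs <- split_on_long_gaps(miss, max_gap)
  meta <- recording_meta(subject_id, sensor_location = "ankle",
                         sampling_rate_hz = rate)
  lapply(segs, function(idx) {
    a <- interp_gaps(accel[idx, , drop = FALSE], time_s[idx])
    g <- interp_gaps(gyro[idx, , drop = FALSE], time_s[idx])
    rec <- imu_recording(time_s[idx], a, g, meta, frame = "raw")
    labeled_recording(rec, as.character(ids[idx]))
  })
}

# Partition 1..N into maximal index runs such that every retained run has
# missing stretches no longer than max_gap (longer stretches are cut out).
split_on_long_gaps <- function(miss, max_gap) {
  n <- length(miss)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  drop <- r$values & r$lengths > max_gap
  keep_mask <- rep(TRUE, n)
  for (i in which(drop)) keep_mask[starts[i]:ends[i]] <- FALSE
  kr <- rle(keep_mask)
  kends <- cumsum(kr$lengths)
  kstarts <- kends - kr$lengths + 1L
  out <- list()
  for (i in seq_along(kr$values)) {
    if (kr$values[i]) out[[length(out) + 1L]] <- kstarts[i]:kends[i]
  }
  out
}

# Linear interpolation of interior NaNs; edge NaNs take the nearest value.
interp_gaps <- function(m, t) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    if (anyNA(v)) {
      ok <- !is.na(v)
      if (sum(ok) < 2L) stop("channel has fewer than 2 valid samples",
                             call. = FALSE)
      m[, j] <- stats::approx(t[ok], v[ok], xout = t, rule = 2)$y
    }
  }
  m
}

#' Read a generic per-sample IMU CSV recording
#'
#' Expected header: `time_s, ax, ay, az, gx, gy, gz, label` with acceleration
#' in m/s^2 and angular velocity in deg/s. Empty labels become `"unlabeled"`.
#' A unit sanity check warns when the median acceleration norm over
#' static-labeled rows falls outside 5-15 m/s^2 (a file still in g units
#' shows a norm near 1).
#'
#' @param path CSV path.
#' @param meta A [recording_meta()] for the recording.
#' @return A [labeled_recording()].
#' @export
read_imu_csv <- function(path, meta) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz", "label")
  if (!all(need %in% names(d))) {
    stop("IMU CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(diff(d$time_s) <= 0)) {
    stop("non-monotonic time column", call. = FALSE)
  }
  lab <- as.character(d$label)
  lab[is.na(lab) | lab == ""] <- "unlabeled"
  accel <- as.matrix(d[, c("ax", "ay", "az")])
  gyro <- as.matrix(d[, c("gx", "gy", "gz")])
  static_rows <- lab == "static"
  if (any(static_rows)) {
    med <- stats::median(norm3(accel[static_rows, , drop = FALSE]))
    if (med < 5 || med > 15) {
      warning(sprintf(
        "median static acceleration norm %.2f outside [5, 15] m/s^2; file may be in g units",
        med))
    }
  }
  rec <- imu_recording(d$time_s, accel, gyro, meta, frame = "raw")
  labeled_recording(rec, lab)
}

#' Write / read a gait mask as CSV
#'
#' Columns `sample_index` (0-based) and `is_walking` (0/1).
#'
#' @param mask A [gait_mask()].
#' @param path Output path.
#' @return `path` invisibly (write); a `gait_mask` (read).
#' @export
write_gait_mask <- function(mask, path) {
  d <- data.frame(sample_index = seq_along(mask$is_walking) - 1L,
                  is_walking = as.integer(mask$is_walking))
  write_csv_checked(d, path,
                    comment = sprintf("# sampling_rate_hz=%g provenance=%s",
                                      mask$sampling_rate_hz, mask$provenance))
  invisible(path)
}

#' @rdname write_gait_mask
#' @export
read_gait_mask <- function(path) {
  hdr <- readLines(path, n = 1L)
  rate <- 100; prov <- "freq"
  if (startsWith(hdr, "#")) {
    rate <- as.numeric(sub(".*sampling_rate_hz=([0-9.e+-]+).*", "\\1", hdr))
    prov <- sub(".*provenance=(\\w+).*", "\\1", hdr)
  }
  d <- utils::read.csv(path, comment.char = "#")
  gait_mask(d$is_walking == 1L, rate, prov)
}

#' Write strides and bouts to CSV
#'
#' Strides are written one row each: `bout_id`, `stride_id`, then 101 columns
#' `p000`..`p100` of time-normalized mediolateral angular velocity. An empty
#' stride set produces a header-only file. Bouts are written as half-open
#' sample intervals `start_sample`, `end_sample` (0-based).
#'
#' @param strides A `stride_set` (see [detect_strides()]).
#' @param bouts A `bout_list` (see [mask_to_bouts()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_strides <- function(strides, path) {
  pcols <- sprintf("p%03d", 0:100)
  if (nrow(strides$strides) == 0L) {
    d <- as.data.frame(matrix(numeric(0), 0, 103,
                              dimnames = list(NULL, c("bout_id", "stride_id", pcols))))
  } else {
    d <- data.frame(bout_id = strides$source_bout,
                    stride_id = seq_len(nrow(strides$strides)) - 1L,
                    strides$strides)
    names(d) <- c("bout_id", "stride_id", pcols)
  }
  write_csv_checked(d, path)
  invisible(path)
}

#' @rdname write_strides
#' @export
read_strides <- function(path) {
  d <- utils::read.csv(path)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  dimnames(m) <- NULL
  stride_set(strides = m, heel_strike_indices = integer(0),
             source_bout = as.integer(d$bout_id))
}

#' @rdname write_strides
#' @export
write_bouts <- function(bouts, path) {
  if (length(bouts$intervals) == 0L) {
    d <- data.frame(start_sample = integer(0), end_sample = integer(0))
  } else {
    m <- do.call(rbind, bouts$intervals)
    d <- data.frame(start_sample = m[, 1], end_sample = m[, 2])
  }
  write_csv_checked(d, path)
  invisible(path)
}

#' @rdname write_strides
#' @export
read_bouts <- function(path, min_duration_s = 0) {
  d <- utils::read.csv(path)
  bout_list(Map(c, d$start_sample, d$end_sample), min_duration_s)
}

#' Write a metrics report to CSV
#'
#' One row per report, mirroring the per-class evaluation-table layout:
#' label, n, accuracy, precision, recall, F1, and Wilson interval bounds.
#'
#' @param reports A named list of `metrics_report` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(reports, path) {
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    ci <- r$wilson %||% list(accuracy = c(NA, NA), precision = c(NA, NA),
                             recall = c(NA, NA))
    data.frame(label = nm, n = r$n,
               accuracy = r$accuracy, precision = r$precision,
               recall = r$recall, f1 = r$f1,
               acc_lo = ci$accuracy[1], acc_hi = ci$accuracy[2],
               prec_lo = ci$precision[1], prec_hi = ci$precision[2],
               rec_lo = ci$recall[1], rec_hi = ci$recall[2])
  })
  write_csv_checked(do.call(rbind, rows), path)
  invisible(path)
}

write_csv_checked <- function(d, path, comment = NULL) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot write to ", path, call. = FALSE)
  on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  utils::write.csv(d, con, row.names = FALSE, quote = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
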