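# Rodrigues rotation taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  axis <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis orthogonal to u
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- w - sum(w * u) * u
    axis <- axis / sqrt(sum(axis^2))
    K <- skew(axis)
    return(diag(3) + 2 * K %*% K)
  }
  axis <- axis / s
  K <- skew(axis)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

skew <- function(a) {
  matrix(c(0, a[3], -a[2],
           -a[3], 0, a[1],
           a[2], -a[1], 0), 3, 3)
}

rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, st, 0, -st, ct, 0, 0, 0, 1), 3, 3)
}

#' Calibrate a recording into the shank coordinate frame
#'
#' Two-step alignment using functional trials. First, the mean acceleration
#' over a quiet-standing interval (i.e., the gravity direction) is rotated
#' onto the vertical +z axis. Second, a rotation about the vertical aligns
#' the first horizontal principal direction of the walking acceleration with
#' the anteroposterior +x axis; the sign of +x is chosen so that the skewness
#' of anteroposterior acceleration during walking is positive (forward
#' progression), with ties broken toward +x. Both rotations are rigid and are
#' applied to accelerometer and gyroscope alike.
#'
#' @param rec An [imu_recording()].
#' @param standing Length-2 sample interval (1-based, inclusive) of quiet
#'   standing, at least 2 s.
#' @param walking Length-2 sample interval of steady walking, at least 5 s.
#' @return The calibrated recording, `frame = "shank"`. The 3x3 rotation used
#'   is attached as attribute `"rotation"`.
#' @export
calibrate_to_shank_frame <- function(rec, standing, walking) {
  rate <- rec$meta$sampling_rate_hz
  si <- standing[1]:standing[2]
  wi <- walking[1]:walking[2]
  if (length(si) < 2 * rate) stop("standing interval must be >= 2 s", call. = FALSE)
  if (length(wi) < 5 * rate) stop("walking interval must be >= 5 s", call. = FALSE)
  a_st <- rec$accel[si, , drop = FALSE]
  nrm <- norm3(a_st)
  if (sqrt(mean((nrm - mean(nrm))^2)) > 1) {
    stop("calibration error: standing interval not quiet (accel norm RMS > 1 m/s^2)",
         call. = FALSE)
  }
  g_vec <- colMeans(a_st)
  R1 <- rotation_between(g_vec, c(0, 0, 1))

  # horizontal principal direction of walking acceleration after levelling
  a_w <- rec$accel[wi, , drop = FALSE] %*% t(R1)
  a_w <- sweep(a_w, 2, colMeans(a_w))
  h <- a_w[, 1:2, drop = FALSE]
  ev <- eigen(crossprod(h) / nrow(h), symmetric = TRUE)
  v <- ev$vectors[, 1]
  R2 <- rot_z(-atan2(v[2], v[1]))
  R <- R2 %*% R1

  ap <- rec$accel[wi, , drop = FALSE] %*% t(R)
  ap1 <- ap[, 1] - mean(ap[, 1])
  sk <- mean(ap1^3) / (mean(ap1^2)^1.5 + 1e-12)
  if (sk < 0) R <- rot_z(pi) %*% R   # flip to forward-progression convention

  out <- rec
  out$accel <- rec$accel %*% t(R)
  out$gyro <- rec$gyro %*% t(R)
  colnames(out$accel) <- c("ax", "ay", "az")
  colnames(out$gyro) <- c("gx", "gy", "gz")
  out$frame <- "shank"
  attr(out, "rotation") <- R
  out
}

#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass (8th-order Butterworth, cutoff
#' 0.4 x target rate, forward-backward) before decimating.
#'
#' @param rec An [imu_recording()].
#' @param target_rate_hz Target rate; the source rate must be an integer
#'   multiple.
#' @return The downsampled recording.
#' @export
downsample <- function(rec, target_rate_hz) {
  src <- rec$meta$sampling_rate_hz
  factor <- src / target_rate_hz
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("source rate %g is not an integer multiple of target %g",
                 src, target_rate_hz), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  if (factor == 1L) return(rec)
  bf <- signal::butter(4, 2 * (0.4 * target_rate_hz) / src, type = "low")
  lp <- function(m) apply(m, 2, function(v) signal::filtfilt(bf, v))
  idx <- seq(1L, length(rec$time_s), by = factor)
  meta <- rec$meta
  meta$sampling_rate_hz <- target_rate_hz
  out <- imu_recording(rec$time_s[idx],
                       lp(rec$accel)[idx, , drop = FALSE],
                       lp(rec$gyro)[idx, , drop = FALSE],
                       meta, frame = rec$frame)
  out
}

#' @rdname downsample
#' @param lrec A [labeled_recording()].
#' @export
downsample_labeled <- function(lrec, target_rate_hz) {
  src <- lrec$recording$meta$sampling_rate_hz
  factor <- as.integer(round(src / target_rate_hz))
  rec <- downsample(lrec$recording, target_rate_hz)
  idx <- seq(1L, length(lrec$labels), by = factor)
  labeled_recording(rec, lrec$labels[idx])
}

#' Harmonize raw activity labels into the seven-class taxonomy
#'
#' Maps every raw label through `mapping` into
#' \{static, walking, running, cycling, stair_ascent, stair_descent, other\};
#' labels mapped to `"drop"` (and raw `"unlabeled"`) become `"unlabeled"`,
#' which downstream windowing treats as removed.
#'
#' @param lrec A [labeled_recording()] with raw labels.
#' @param mapping Named list/character: raw label -> class or `"drop"`.
#' @return The recording with harmonized labels.
#' @export
harmonize_labels <- function(lrec, mapping) {
  mapping <- unlist(mapping)
  raw <- unique(lrec$labels)
  raw <- setdiff(raw, "unlabeled")
  missing <- setdiff(raw, names(mapping))
  if (length(missing) > 0) {
    stop("unmapped raw label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ok <- mapping %in% c(ACTIVITY_CLASSES, "drop")
  if (!all(ok)) {
    stop("mapping targets must be one of the seven classes or 'drop': ",
         paste(unique(mapping[!ok]), collapse = ", "), call. = FALSE)
  }
  new <- lrec$labels
  hit <- new %in% names(mapping)
  new[hit] <- unname(mapping[new[hit]])
  new[new == "drop"] <- "unlabeled"
  labeled_recording(lrec$recording, new)
}

#' Trim the edges of every contiguous activity run
#'
#' Marks the first and last `n_trim` samples of each maximal same-label run
#' as `"unlabeled"` (removed), to exclude transition periods and labelling
#' inaccuracies; runs of length <= 2 * n_trim are removed entirely.
#'
#' @param lrec A [labeled_recording()].
#' @param n_trim Samples trimmed from each end of each run (default 500).
#' @return The recording with trimmed labels.
#' @export
trim_activity_edges <- function(lrec, n_trim = 500L) {
  lab <- lrec$labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (r$values[i] == "unlabeled") next
    if (r$lengths[i] <= 2L * n_trim) {
      lab[starts[i]:ends[i]] <- "unlabeled"
    } else {
      lab[starts[i]:(starts[i] + n_trim - 1L)] <- "unlabeled"
      lab[(ends[i] - n_trim + 1L):ends[i]] <- "unlabeled"
    }
  }
  labeled_recording(lrec$recording, lab)
}

#' Windowed model input
#'
#' @param windows W x window_sz x 6 array (channel order ax, ay, az, gx, gy,
#'   gz).
#' @param labels Length-W class labels.
#' @param starts Length-W 0-based start sample of each window.
#' @param window_sz Window length in samples.
#' @param sampling_rate_hz Rate of the source recording.
#' @return An object of class `window_set`.
#' @export
window_set <- function(windows, labels, starts, window_sz, sampling_rate_hz) {
  stopifnot(length(dim(windows)) == 3L,
            dim(windows)[1] == length(labels),
            length(starts) == length(labels))
  structure(list(windows = windows, labels = as.character(labels),
                 starts = as.integer(starts), window_sz = as.integer(window_sz),
                 n_channels = dim(windows)[3],
                 sampling_rate_hz = sampling_rate_hz),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples x %d channels @ %g Hz\n",
              dim(x$windows)[1], x$window_sz, x$n_channels,
              x$sampling_rate_hz))
  if (dim(x$windows)[1] > 0) {
    tab <- sort(table(x$labels), decreasing = TRUE)
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Segment a labeled recording into sliding windows
#'
#' Windows of `window_seconds * rate` samples with the configured overlap are
#' taken inside each maximal contiguous run of one (non-"unlabeled") label,
#' so no window spans a label boundary or removed samples. Each window
#' carries its run's label. Runs shorter than one window contribute no
#' windows.
#'
#' @param lrec A [labeled_recording()] at the target rate.
#' @param cfg A `run_config` (uses `preprocess$window_seconds` and
#'   `preprocess$overlap_fraction`).
#' @return A [window_set()].
#' @export
segment_windows <- function(lrec, cfg = default_config()) {
  rate <- lrec$recording$meta$sampling_rate_hz
  wsz <- as.integer(round(cfg$preprocess$window_seconds * rate))
  hop <- as.integer(round(wsz * (1 - cfg$preprocess$overlap_fraction)))
  if (hop < 1L) stop("overlap too large: hop < 1 sample", call. = FALSE)
  lab <- lrec$labels
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sig <- cbind(lrec$recording$accel, lrec$recording$gyro)

  win_starts <- integer(0)
  win_labels <- character(0)
  for (i in seq_along(r$values)) {
    if (r$values[i] == "unlabeled") next
    n_run <- r$lengths[i]
    if (n_run < wsz) next
    w <- (n_run - wsz) %/% hop + 1L
    s0 <- starts[i] + hop * (seq_len(w) - 1L)
    win_starts <- c(win_starts, s0)
    win_labels <- c(win_labels, rep(r$values[i], w))
  }
  W <- length(win_starts)
  arr <- array(0, dim = c(W, wsz, 6L))
  for (k in seq_len(W)) {
    arr[k, , ] <- sig[win_starts[k]:(win_starts[k] + wsz - 1L), ]
  }
  window_set(arr, win_labels, win_starts - 1L, wsz, rate)
}

#' Drop static windows that are not actually still
#'
#' For static-labeled windows, computes the RMS of the deviation of the
#' acceleration norm from the window's own gravity estimate (the mean norm)
#' and removes windows whose RMS is not strictly below `limit`. Non-static
#' windows pass through untouched. Must be applied before scaling, while the
#' windows are still in m/s^2.
#'
#' @param ws A [window_set()].
#' @param limit RMS limit in m/s^2 (default 1, strict "less than").
#' @return The filtered [window_set()].
#' @export
filter_static_windows <- function(ws, limit = 1.0) {
  W <- dim(ws$windows)[1]
  keep <- rep(TRUE, W)
  for (k in seq_len(W)) {
    if (ws$labels[k] != "static") next
    a <- ws$windows[k, , 1:3]
    nrm <- sqrt(rowSums(a^2))
    rms <- sqrt(mean((nrm - mean(nrm))^2))
    keep[k] <- rms < limit
  }
  window_set(ws$windows[keep, , , drop = FALSE], ws$labels[keep],
             ws$starts[keep], ws$window_sz, ws$sampling_rate_hz)
}

#' Participant-specific standardization fitted on walking data
#'
#' Fits a per-channel standardizing transform (subtract mean, divide by
#' standard deviation) on the walking-labeled samples of one participant's
#' recording; the transform is then applied to all of that participant's
#' windows with [apply_scaler()]. Channels with standard deviation below
#' 1e-8 keep scale 1 (degenerate-channel guard).
#'
#' @param lrec A [labeled_recording()] containing at least one
#'   walking-labeled sample.
#' @return An object of class `scaler_params` (fields `mean`, `sd`, length 6
#'   each).
#' @export
fit_participant_scaler <- function(lrec) {
  wi <- lrec$labels == "walking"
  if (!any(wi)) stop("scaler requires walking section", call. = FALSE)
  sig <- cbind(lrec$recording$accel, lrec$recording$gyro)[wi, , drop = FALSE]
  mu <- colMeans(sig)
  sd_ <- apply(sig, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-8] <- 1
  structure(list(mean = mu, sd = sd_), class = "scaler_params")
}

#' @rdname fit_participant_scaler
#' @param ws A [window_set()] from the same participant.
#' @param p A `scaler_params` object.
#' @export
apply_scaler <- function(ws, p) {
  out <- ws
  for (ch in seq_len(ws$n_channels)) {
    out$windows[, , ch] <- (ws$windows[, , ch] - p$mean[ch]) / p$sd[ch]
  }
  out
}
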