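#' Walking bouts as half-open sample intervals
#'
#' @param intervals List of length-2 vectors `(start, end)`: half-open
#'   0-based sample intervals, disjoint, sorted, non-empty.
#' @param min_duration_s Minimum bout duration retained (s).
#' @return An object of class `bout_list`.
#' @export
bout_list <- function(intervals, min_duration_s = 0) {
  if (length(intervals) > 0) {
    m <- do.call(rbind, lapply(intervals, as.numeric))
    stopifnot(all(m[, 2] > m[, 1]))
    if (nrow(m) > 1) stopifnot(all(m[-1, 1] >= m[-nrow(m), 2]))
  }
  structure(list(intervals = lapply(intervals, as.integer),
                 min_duration_s = min_duration_s),
            class = "bout_list")
}

#' @export
print.bout_list <- function(x, ...) {
  cat(sprintf("<bout_list> %d bouts (min duration %gs)\n",
              length(x$intervals), x$min_duration_s))
  invisible(x)
}

#' Convert window predictions to a per-sample walking mask
#'
#' For each sample, the proportion of covering windows predicted "walking" is
#' computed; the sample is walking when that proportion is strictly greater
#' than 0.5. Samples covered by no window are not walking.
#'
#' @param preds A `prediction_set` (see [predict.har_model()]), or any list
#'   with `starts` (0-based), `window_sz`, `predicted_labels` and
#'   `sampling_rate_hz`.
#' @param n_samples Length of the source recording.
#' @return A [gait_mask()] with provenance `"ml_model"`.
#' @export
predictions_to_mask <- function(preds, n_samples) {
  cover <- integer(n_samples)
  votes <- integer(n_samples)
  is_walk <- preds$predicted_labels == "walking"
  for (i in seq_along(preds$starts)) {
    s <- preds$starts[i] + 1L
    e <- min(s + preds$window_sz - 1L, n_samples)
    if (s > n_samples) next
    cover[s:e] <- cover[s:e] + 1L
    if (is_walk[i]) votes[s:e] <- votes[s:e] + 1L
  }
  gait_mask(cover > 0L & votes > cover / 2,
            preds$sampling_rate_hz %||% 100, "ml_model")
}

#' Extract walking bouts from a gait mask
#'
#' Maximal runs of `TRUE` become half-open `[start, end)` intervals
#' (0-based); runs shorter than `min_duration_s` are dropped.
#'
#' @param mask A [gait_mask()].
#' @param min_duration_s Minimum bout duration (s).
#' @return A [bout_list()].
#' @export
mask_to_bouts <- function(mask, min_duration_s = 0) {
  r <- rle(mask$is_walking)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_n <- min_duration_s * mask$sampling_rate_hz
  keep <- which(r$values & r$lengths >= min_n)
  bout_list(lapply(keep, function(i) c(starts[i] - 1L, ends[i])),
            min_duration_s)
}

#' Set of time-normalized strides
#'
#' @param strides S x 101 matrix of time-normalized mediolateral angular
#'   velocity (deg/s), one row per stride.
#' @param heel_strike_indices 1-based sample indices of the detected heel
#'   strikes (strictly increasing; length S + 1 when strides are contiguous).
#' @param source_bout Integer bout id per stride.
#' @param midswing_indices Optional 1-based mid-swing peak sample indices.
#' @return An object of class `stride_set`.
#' @export
stride_set <- function(strides, heel_strike_indices, source_bout,
                       midswing_indices = integer(0)) {
  strides <- as.matrix(strides)
  if (nrow(strides) > 0 && ncol(strides) != 101L) {
    stop("stride rows must have exactly 101 points", call. = FALSE)
  }
  if (length(heel_strike_indices) > 1 &&
      any(diff(heel_strike_indices) <= 0)) {
    stop("heel-strike indices must be strictly increasing", call. = FALSE)
  }
  structure(list(strides = strides,
                 heel_strike_indices = as.integer(heel_strike_indices),
                 source_bout = as.integer(source_bout),
                 midswing_indices = as.integer(midswing_indices)),
            class = "stride_set")
}

#' @export
print.stride_set <- function(x, ...) {
  cat(sprintf("<stride_set> %d strides (%d heel strikes, %d mid-swing peaks)\n",
              nrow(x$strides), length(x$heel_strike_indices),
              length(x$midswing_indices)))
  invisible(x)
}

# local maxima with minimum height and minimum separation (greedy by height)
find_peaks_minsep <- function(v, min_height, min_sep) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  cand <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  cand <- cand[v[cand] >= min_height]
  if (length(cand) == 0L) return(integer(0))
  cand <- cand[order(v[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Detect strides within a walking bout
#'
#' Mid-swing peaks are located as local maxima of the mediolateral angular
#' velocity with height at least `midswing_min_height_dps` and separation at
#' least `midswing_min_separation_s`. For each successive pair of mid-swing
#' peaks the heel strike is the largest resultant-acceleration peak in the
#' first half of the interval (left endpoint included). Strides run from heel
#' strike to next heel strike; strides with duration outside
#' `stride_duration_range_s` are discarded. Each retained stride is
#' time-normalized to 101 points.
#'
#' @param rec A calibrated [imu_recording()].
#' @param bout Length-2 half-open 0-based sample interval `(start, end)`.
#' @param cfg A `run_config` (uses the `stride` block).
#' @param bout_id Integer id recorded with each stride.
#' @return A [stride_set()]; empty when fewer than two mid-swing peaks are
#'   found.
#' @export
detect_strides <- function(rec, bout, cfg = default_config(), bout_id = 0L) {
  rate <- rec$meta$sampling_rate_hz
  s <- bout[1] + 1L
  e <- bout[2]
  if (s < 1L || e > length(rec$time_s)) {
    stop("bout outside recording", call. = FALSE)
  }
  ml <- rec$gyro[s:e, 2]
  anorm <- norm3(rec$accel[s:e, , drop = FALSE])
  sc <- cfg$stride
  ms <- find_peaks_minsep(ml, sc$midswing_min_height_dps,
                          sc$midswing_min_separation_s * rate)
  empty <- stride_set(matrix(numeric(0), 0, 101), integer(0), integer(0))
  if (length(ms) < 2L) {
    empty$midswing_indices <- as.integer(ms + s - 1L)
    return(empty)
  }
  hs <- integer(length(ms) - 1L)
  for (i in seq_len(length(ms) - 1L)) {
    half_end <- ms[i] + (ms[i + 1L] - ms[i]) %/% 2L
    seg <- anorm[ms[i]:half_end]
    hs[i] <- ms[i] + which.max(seg) - 1L
  }
  strides <- list()
  src <- integer(0)
  for (i in seq_len(length(hs) - 1L)) {
    dur <- (hs[i + 1L] - hs[i]) / rate
    if (dur < sc$stride_duration_range_s[1] ||
        dur > sc$stride_duration_range_s[2]) next
    strides[[length(strides) + 1L]] <-
      normalize_stride_vec(ml[hs[i]:hs[i + 1L]])
    src <- c(src, bout_id)
  }
  m <- if (length(strides) > 0) do.call(rbind, strides) else
    matrix(numeric(0), 0, 101)
  stride_set(m, hs + s - 1L, src, midswing_indices = ms + s - 1L)
}

normalize_stride_vec <- function(v) {
  n <- length(v)
  if (n < 2L) stop("stride must span at least 2 samples", call. = FALSE)
  stats::approx(seq(0, 1, length.out = n), v,
                xout = seq(0, 1, length.out = 101))$y
}

#' Time-normalize one stride to 101 points
#'
#' Linear interpolation of the mediolateral angular velocity between a pair
#' of heel strikes (inclusive) onto 101 equally spaced points.
#'
#' @param rec An [imu_recording()].
#' @param hs_pair Length-2 1-based sample indices (heel strike, next heel
#'   strike).
#' @return Numeric vector of length 101.
#' @export
normalize_stride <- function(rec, hs_pair) {
  normalize_stride_vec(rec$gyro[hs_pair[1]:hs_pair[2], 2])
}

#' Ensemble-average a stride set
#'
#' @param strides A [stride_set()].
#' @return List with `mean` and `sd`, each length 101.
#' @export
ensemble_average <- function(strides) {
  if (nrow(strides$strides) == 0L) {
    stop("cannot ensemble-average an empty stride set", call. = FALSE)
  }
  m <- colMeans(strides$strides)
  s <- apply(strides$strides, 2, stats::sd)
  if (nrow(strides$strides) == 1L) s <- rep(0, 101)
  list(mean = m, sd = s)
}

#' Plot the ensemble-averaged stride waveform
#'
#' Mean time-normalized mediolateral angular velocity with a +/- 1 SD band.
#'
#' @param x A `stride_set`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stride_set <- function(x, ...) {
  ea <- ensemble_average(x)
  pct <- 0:100
  graphics::plot(pct, ea$mean, type = "n",
                 ylim = range(ea$mean - ea$sd, ea$mean + ea$sd),
                 xlab = "% gait cycle",
                 ylab = "ML angular velocity (deg/s)", ...)
  graphics::polygon(c(pct, rev(pct)),
                    c(ea$mean + ea$sd, rev(ea$mean - ea$sd)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(pct, ea$mean, lwd = 2, col = "steelblue4")
  invisible(x)
}
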