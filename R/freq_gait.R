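#' Configuration for the harmonic frequency gait detector
#'
#' Defaults follow the shank-adapted parameterization: the mediolateral
#' angular velocity analysed in 10 s windows; a window is "active" when its
#' RMS exceeds 50 deg/s; an active window is "gait" when spectral peaks with
#' one-sided amplitude-spectrum prominence of at least 5 deg/s are found at a
#' minimum of two of the first four harmonics of the fundamental cadence.
#'
#' @param window_seconds Analysis window length (s).
#' @param hop_seconds Hop between successive windows (s).
#' @param rest_threshold Active-window RMS threshold (deg/s).
#' @param n_harmonics Number of harmonics examined.
#' @param min_peaks Minimum harmonics with a peak for a "gait" call.
#' @param peak_prominence Spectral peak prominence threshold, in the physical
#'   units of the analysed signal (deg/s for gyroscope channels).
#' @param locomotor_band_hz Search band for the fundamental (Hz).
#' @param harmonic_tolerance Fractional tolerance: harmonic k may lie within
#'   `k * f0 * (1 +/- tolerance)`.
#' @param signal Channel analysed: `"ml_gyro"`, `"v_accel"`, `"accel_norm"`,
#'   or `"gyro_norm"`.
#' @return An object of class `freq_detector_config`.
#' @export
freq_detector_config <- function(window_seconds = 10, hop_seconds = 5,
                                 rest_threshold = 50, n_harmonics = 4L,
                                 min_peaks = 2L, peak_prominence = 5,
                                 locomotor_band_hz = c(0.5, 3.0),
                                 harmonic_tolerance = 0.15,
                                 signal = c("ml_gyro", "v_accel",
                                            "accel_norm", "gyro_norm")) {
  signal <- match.arg(signal)
  stopifnot(min_peaks <= n_harmonics,
            locomotor_band_hz[1] < locomotor_band_hz[2])
  structure(list(window_seconds = window_seconds, hop_seconds = hop_seconds,
                 rest_threshold = rest_threshold,
                 n_harmonics = as.integer(n_harmonics),
                 min_peaks = as.integer(min_peaks),
                 peak_prominence = peak_prominence,
                 locomotor_band_hz = locomotor_band_hz,
                 harmonic_tolerance = harmonic_tolerance,
                 signal = signal),
            class = "freq_detector_config")
}

extract_detector_signal <- function(rec, signal) {
  switch(signal,
         ml_gyro = rec$gyro[, 2],
         v_accel = rec$accel[, 3],
         accel_norm = norm3(rec$accel),
         gyro_norm = norm3(rec$gyro))
}

#' Is a window "active"?
#'
#' A window is active when the root mean square of the raw (untrended)
#' segment exceeds the resting threshold.
#'
#' @param segment Numeric signal window.
#' @param cfg A [freq_detector_config()].
#' @return Logical.
#' @export
is_active_window <- function(segment, cfg = freq_detector_config()) {
  sqrt(mean(segment^2)) > cfg$rest_threshold
}

# One-sided amplitude spectrum: the segment is detrended (linear), tapered
# with a Hann window, and FFT magnitudes are scaled as 2|X|/N. With the Hann
# taper a pure sinusoid of amplitude A reads ~A/2 (the taper's coherent
# gain), so the prominence threshold of 5 corresponds to a ~10 deg/s
# harmonic amplitude; keeping the full window length preserves the 0.1 Hz
# resolution needed to separate slow-gait harmonics, and the uncompensated
# scaling keeps broadband-noise fluctuations well below the prominence
# threshold.
amplitude_spectrum <- function(segment, rate) {
  n <- length(segment)
  t <- seq_len(n)
  seg <- stats::lm.fit(cbind(1, t), segment)$residuals
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  X <- stats::fft(seg * w)
  half <- seq_len(n %/% 2 + 1L)
  list(freq = (half - 1L) * rate / n,
       amp = 2 * Mod(X[half]) / n)
}

# Local maxima of v with their topographic prominence. Prominence of a peak
# is its height minus the higher of the two minima separating it from the
# nearest higher terrain on each side (window edge if none).
spectral_peaks <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(index = integer(0), height = numeric(0),
                                prominence = numeric(0)))
  is_peak <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  if (length(is_peak) == 0L) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(is_peak, function(i) {
    h <- v[i]
    # walk left until higher terrain
    left_min <- h
    j <- i - 1L
    while (j >= 1L && v[j] <= h) {
      if (v[j] < left_min) left_min <- v[j]
      j <- j - 1L
    }
    if (j < 1L && left_min == h) left_min <- min(v[1:i])
    right_min <- h
    j <- i + 1L
    while (j <= n && v[j] <= h) {
      if (v[j] < right_min) right_min <- v[j]
      j <- j + 1L
    }
    if (j > n && right_min == h) right_min <- min(v[i:n])
    h - max(left_min, right_min)
  }, numeric(1))
  data.frame(index = is_peak, height = v[is_peak], prominence = prom)
}

#' Classify one active window as gait / not gait
#'
#' Computes the one-sided amplitude spectrum (detrended, Hann-tapered,
#' `2|X|/N` scaling), locates the fundamental as the most prominent
#' qualifying peak (prominence at least `peak_prominence`, so an unstructured
#' spectrum yields no fundamental) inside the locomotor band, and checks the
#' first `n_harmonics` harmonics: harmonic k "has a peak" when a local
#' spectral maximum with prominence at least `peak_prominence` lies within
#' `k * f0 * (1 +/- harmonic_tolerance)`. The window is gait when at least
#' `min_peaks` harmonics have peaks. Windows with no qualifying peak in the
#' locomotor band are not gait.
#'
#' @inheritParams is_active_window
#' @param rate Sampling rate (Hz).
#' @return Logical: gait or not.
#' @export
classify_window <- function(segment, rate, cfg = freq_detector_config()) {
  sp <- amplitude_spectrum(segment, rate)
  pk <- spectral_peaks(sp$amp)
  if (nrow(pk) == 0L) return(FALSE)
  f_pk <- sp$freq[pk$index]
  in_band <- f_pk >= cfg$locomotor_band_hz[1] &
    f_pk <= cfg$locomotor_band_hz[2] &
    pk$prominence >= cfg$peak_prominence
  if (!any(in_band)) return(FALSE)
  band_pk <- pk[in_band, , drop = FALSE]
  f0 <- sp$freq[band_pk$index[which.max(band_pk$prominence)]]
  strong <- pk$prominence >= cfg$peak_prominence
  n_found <- 0L
  for (k in seq_len(cfg$n_harmonics)) {
    lo <- k * f0 * (1 - cfg$harmonic_tolerance)
    hi <- k * f0 * (1 + cfg$harmonic_tolerance)
    if (any(strong & f_pk >= lo & f_pk <= hi)) n_found <- n_found + 1L
  }
  n_found >= cfg$min_peaks
}

#' Detect gait with the harmonic frequency heuristic
#'
#' Slides windows of `window_seconds` at a hop of `hop_seconds` over the
#' chosen channel; each window is classified gait when it is active
#' ([is_active_window()]) and shows harmonic structure ([classify_window()]).
#' Window calls are aggregated to a per-sample Boolean mask: a sample is
#' walking when strictly more than half of the windows covering it are gait
#' (the same majority rule used to aggregate the classifier's window
#' predictions, so the two methods are directly comparable). Trailing samples
#' covered by no window inherit the last window's class.
#'
#' @param rec A calibrated shank-frame [imu_recording()].
#' @param cfg A [freq_detector_config()].
#' @return A [gait_mask()] with provenance `"freq"`.
#' @export
detect_gait <- function(rec, cfg = freq_detector_config()) {
  rate <- rec$meta$sampling_rate_hz
  x <- extract_detector_signal(rec, cfg$signal)
  n <- length(x)
  wsz <- as.integer(round(cfg$window_seconds * rate))
  hop <- as.integer(round(cfg$hop_seconds * rate))
  if (n < wsz) {
    warning("recording shorter than one analysis window; returning all-false mask")
    return(gait_mask(rep(FALSE, n), rate, "freq"))
  }
  starts <- seq(1L, n - wsz + 1L, by = hop)
  calls <- vapply(starts, function(s) {
    seg <- x[s:(s + wsz - 1L)]
    is_active_window(seg, cfg) && classify_window(seg, rate, cfg)
  }, logical(1))

  cover <- integer(n)
  votes <- integer(n)
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + wsz - 1L)
    cover[idx] <- cover[idx] + 1L
    if (calls[i]) votes[idx] <- votes[idx] + 1L
  }
  mask <- cover > 0L & votes > cover / 2
  tail_start <- starts[length(starts)] + wsz
  if (tail_start <= n) mask[tail_start:n] <- calls[length(calls)]
  gait_mask(mask, rate, "freq")
}
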