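#' Gait profile for the synthetic signal generator
#'
#' Maps a walking speed to the parameters of the synthetic gait template. The
#' speed-to-cadence/amplitude mapping is a small lookup (0.3 m/s -> 0.45 Hz
#' stride frequency and 40% of the reference mid-swing amplitude; 1.0 m/s ->
#' 0.9 Hz at the reference amplitude; 1.4 m/s -> 1.05 Hz, high amplitude),
#' linearly interpolated in between, chosen to reproduce the qualitative
#' speed-dependent detectability of gait; none of the values is claimed to be
#' physiologically exact, and all are overridable. Speed strata follow the
#' clinical convention: slow < 0.8, average 0.8-1.2, fast > 1.2 m/s.
#'
#' @param gait_speed_mps Walking speed (m/s).
#' @param stride_frequency_hz Override the stride (cycle) frequency.
#' @param midswing_amplitude_dps Override the mid-swing gyro peak amplitude.
#' @param heelstrike_amplitude_mps2 Override the heel-strike impulse size.
#' @param harmonic_amplitudes Fractions of the fundamental used for the
#'   anteroposterior acceleration oscillation (k = 1..4).
#' @param jitter Cycle-time coefficient of variation.
#' @param noise_sd Per-channel Gaussian noise: `accel` (m/s^2), `gyro`
#'   (deg/s).
#' @return An object of class `gait_profile`.
#' @export
gait_profile <- function(gait_speed_mps = 1.0,
                         stride_frequency_hz = NULL,
                         midswing_amplitude_dps = NULL,
                         heelstrike_amplitude_mps2 = NULL,
                         harmonic_amplitudes = c(1, 0.5, 0.25, 0.12),
                         jitter = 0.03,
                         noise_sd = c(accel = 0.05, gyro = 1)) {
  sp <- c(0.3, 1.0, 1.4)
  f0_tab <- c(0.45, 0.9, 1.05)
  amp_tab <- c(160, 400, 500)
  hs_tab <- c(2, 5, 7)
  f0 <- stride_frequency_hz %||%
    stats::approx(sp, f0_tab, gait_speed_mps, rule = 2)$y
  amp <- midswing_amplitude_dps %||%
    stats::approx(sp, amp_tab, gait_speed_mps, rule = 2)$y
  hs <- heelstrike_amplitude_mps2 %||%
    stats::approx(sp, hs_tab, gait_speed_mps, rule = 2)$y
  stopifnot(f0 > 0.3, f0 < 2.5, amp >= 0, hs >= 0)
  stratum <- if (gait_speed_mps < 0.8) "slow"
             else if (gait_speed_mps <= 1.2) "average" else "fast"
  structure(list(gait_speed_mps = gait_speed_mps,
                 stride_frequency_hz = f0,
                 midswing_amplitude_dps = amp,
                 heelstrike_amplitude_mps2 = hs,
                 harmonic_amplitudes = harmonic_amplitudes,
                 jitter = jitter, noise_sd = noise_sd,
                 stratum = stratum),
            class = "gait_profile")
}

GRAVITY <- 9.81

#' Synthesize a walking segment
#'
#' Builds a template-based gait signal: the mediolateral angular velocity is
#' a train of one dominant positive mid-swing bump per cycle (Gaussian, width
#' 8% of the cycle) plus a smaller negative stance bump, so its spectrum
#' carries the stride-frequency fundamental and several harmonics. The
#' resultant acceleration is gravity plus a planted heel-strike transient (a
#' decaying 15 Hz oscillation peaking exactly at the planted time, 30% of a
#' cycle after each mid-swing, i.e. inside the first half of the
#' mid-swing-to-mid-swing interval) and a small anteroposterior oscillation.
#' Cycle times are jittered by the profile's CV and Gaussian channel noise is
#' added. Planted event times are returned as ground truth.
#'
#' @param profile A [gait_profile()].
#' @param duration_s Segment duration (s); must cover at least 2 cycles.
#' @param rate Sampling rate (Hz).
#' @param seed RNG seed.
#' @param n_cycles Plant exactly this many cycles (overrides `duration_s`).
#' @return A [labeled_recording()] labeled `"walking"`, with attributes
#'   `events` (list of 1-based `midswing` and `heelstrike` sample indices)
#'   and `truth` (logical walking mask).
#' @export
synth_walking <- function(profile, duration_s, rate = 100, seed = 1,
                          n_cycles = NULL) {
  set.seed(seed)
  f0 <- profile$stride_frequency_hz
  Tc0 <- 1 / f0
  if (is.null(n_cycles)) {
    if (duration_s < 2 * Tc0) {
      stop("duration must cover at least 2 gait cycles", call. = FALSE)
    }
    n_cycles <- floor(duration_s / Tc0)
    durations <- Tc0 * pmax(0.5, 1 + profile$jitter * stats::rnorm(n_cycles))
    # drop cycles that no longer fit
    keep <- cumsum(durations) <= duration_s
    n_cycles <- sum(keep)
    durations <- durations[keep]
    n <- as.integer(round(duration_s * rate))
  } else {
    durations <- Tc0 * pmax(0.5, 1 + profile$jitter * stats::rnorm(n_cycles))
    duration_s <- sum(durations) + 0.5 * Tc0
    n <- as.integer(round(duration_s * rate))
  }
  t <- (seq_len(n) - 1) / rate
  cyc_start <- c(0, cumsum(durations))[seq_len(n_cycles)] + 0.05 * Tc0

  ml <- numeric(n)
  ap <- numeric(n)
  az <- rep(GRAVITY, n)
  ms_idx <- integer(n_cycles)
  hs_idx <- integer(n_cycles)
  for (i in seq_len(n_cycles)) {
    Tc <- durations[i]
    tm <- cyc_start[i] + 0.25 * Tc
    th <- cyc_start[i] + 0.55 * Tc            # tm + 0.3 Tc, inside first half
    ml <- ml + profile$midswing_amplitude_dps *
      exp(-((t - tm) / (0.08 * Tc))^2)
    ml <- ml - 0.3 * profile$midswing_amplitude_dps *
      exp(-((t - cyc_start[i] - 0.7 * Tc) / (0.15 * Tc))^2)
    post <- t >= th
    az[post] <- az[post] + profile$heelstrike_amplitude_mps2 *
      exp(-(t[post] - th) / 0.05) * cos(2 * pi * 15 * (t[post] - th))
    ms_idx[i] <- as.integer(round(tm * rate)) + 1L
    hs_idx[i] <- as.integer(round(th * rate)) + 1L
  }
  a1 <- 1.2
  for (k in seq_along(profile$harmonic_amplitudes)) {
    ap <- ap + a1 * profile$harmonic_amplitudes[k] *
      sin(2 * pi * k * f0 * t + 0.3 * k)
  }
  # mild positive skew on the anteroposterior axis (forward progression)
  ap <- ap + 0.3 * a1 * pmax(sin(2 * pi * f0 * t), 0)^2

  accel <- cbind(ap, 0.3 * sin(2 * pi * f0 * t + 1), az) +
    matrix(stats::rnorm(3 * n, 0, profile$noise_sd[["accel"]]), n, 3)
  gyro <- cbind(0.2 * ml, ml, 0.15 * ml) +
    matrix(stats::rnorm(3 * n, 0, profile$noise_sd[["gyro"]]), n, 3)

  meta <- recording_meta("synthetic", "proximal_shank", rate)
  rec <- imu_recording(t, accel, gyro, meta, frame = "shank")
  out <- labeled_recording(rec, rep("walking", n))
  attr(out, "events") <- list(midswing = ms_idx[ms_idx <= n],
                              heelstrike = hs_idx[hs_idx <= n])
  attr(out, "truth") <- rep(TRUE, n)
  out
}

# band-limited Gaussian noise via random-phase spectral synthesis,
# scaled to a target RMS
band_noise <- function(n, rate, f_lo, f_hi, rms) {
  freq <- (0:(n - 1)) * rate / n
  half <- freq <= rate / 2
  env <- as.numeric(freq >= f_lo & freq <= f_hi & half)
  X <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * env
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x / s * rms
}

#' Synthesize a static (non-movement) segment
#'
#' Gravity along +z plus Gaussian channel noise; the RMS deviation of the
#' acceleration norm is far below the 1 m/s^2 static-window gate.
#'
#' @param duration_s Duration (s).
#' @param rate Sampling rate (Hz).
#' @param noise_sd Named vector: `accel` (m/s^2), `gyro` (deg/s).
#' @param seed RNG seed.
#' @return A [labeled_recording()] labeled `"static"` with a `truth`
#'   attribute (all `FALSE`).
#' @export
synth_static <- function(duration_s, rate = 100,
                         noise_sd = c(accel = 0.05, gyro = 1), seed = 1) {
  set.seed(seed)
  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1) / rate
  accel <- cbind(0, 0, GRAVITY) [rep(1, n), ] +
    matrix(stats::rnorm(3 * n, 0, noise_sd[["accel"]]), n, 3)
  gyro <- matrix(stats::rnorm(3 * n, 0, noise_sd[["gyro"]]), n, 3)
  meta <- recording_meta("synthetic", "proximal_shank", rate)
  out <- labeled_recording(imu_recording(t, accel, gyro, meta, "shank"),
                           rep("static", n))
  attr(out, "truth") <- rep(FALSE, n)
  out
}

#' Synthesize a non-gait "other" activity segment
#'
#' Emulates active but non-periodic movement (housework-like): the gyroscope
#' is dominated by strong, slowly wandering motion (random-phase noise in the
#' 0.3-0.65 Hz band) with a weak broadband component up to 8 Hz, so windows
#' are "active" (mediolateral RMS above the 50 deg/s rest threshold) yet the
#' spectrum has no stable harmonic structure above the peak-prominence
#' threshold at harmonic positions.
#'
#' @inheritParams synth_static
#' @return A [labeled_recording()] labeled `"other"` with a `truth`
#'   attribute (all `FALSE`).
#' @export
synth_other <- function(duration_s, rate = 100, seed = 1) {
  set.seed(seed)
  n <- as.integer(round(duration_s * rate))
  t <- (seq_len(n) - 1) / rate
  gchan <- function(rms_lo) {
    band_noise(n, rate, 0.3, 0.65, rms_lo) +
      band_noise(n, rate, 1.2, 8, 8) +
      stats::rnorm(n, 0, 2)
  }
  gyro <- cbind(gchan(70), gchan(100), gchan(60))
  accel <- cbind(band_noise(n, rate, 0.3, 0.65, 1.2),
                 band_noise(n, rate, 0.3, 0.65, 1.0),
                 GRAVITY + band_noise(n, rate, 0.3, 0.65, 1.2)) +
    matrix(stats::rnorm(3 * n, 0, 0.3), n, 3)
  meta <- recording_meta("synthetic", "proximal_shank", rate)
  out <- labeled_recording(imu_recording(t, accel, gyro, meta, "shank"),
                           rep("other", n))
  attr(out, "truth") <- rep(FALSE, n)
  out
}

#' Default activity schedules
#'
#' `"clinical"` emulates the labeled in-clinic composition (about 48% static
#' and 52% walking); `"three_class"` adds an "other" segment for
#' classifier-training cohorts.
#'
#' @param kind Schedule template name.
#' @param walking_speed_mps Walking speed used for walking segments.
#' @return A list of segment descriptors (label, duration_s, speed).
#' @export
default_schedule <- function(kind = c("clinical", "three_class"),
                             walking_speed_mps = 1.0) {
  kind <- match.arg(kind)
  if (kind == "clinical") {
    list(list(label = "static", duration_s = 115),
         list(label = "walking", duration_s = 125,
              speed = walking_speed_mps))
  } else {
    list(list(label = "static", duration_s = 30),
         list(label = "walking", duration_s = 30, speed = walking_speed_mps),
         list(label = "other", duration_s = 30))
  }
}

#' Synthesize one labeled recording from an activity schedule
#'
#' Concatenates per-activity segments; ground-truth walking mask and planted
#' event indices (offset into the full recording) are attached as attributes
#' `truth` and `events`.
#'
#' @param schedule List of segment descriptors (see [default_schedule()]).
#' @param profile Base [gait_profile()] for walking segments (per-segment
#'   `speed` overrides the speed).
#' @param rate Sampling rate (Hz).
#' @param seed RNG seed.
#' @param subject_id Subject identifier.
#' @return A [labeled_recording()].
#' @export
synth_recording <- function(schedule, profile = gait_profile(), rate = 100,
                            seed = 1, subject_id = "synthetic") {
  set.seed(seed)
  seg_seeds <- sample.int(.Machine$integer.max - 1L, length(schedule))
  segs <- vector("list", length(schedule))
  for (i in seq_along(schedule)) {
    s <- schedule[[i]]
    segs[[i]] <- switch(
      s$label,
      walking = {
        p <- if (!is.null(s$speed)) {
          pr <- gait_profile(s$speed, jitter = profile$jitter,
                             noise_sd = profile$noise_sd)
          pr$midswing_amplitude_dps <-
            pr$midswing_amplitude_dps * (profile$amp_factor %||% 1)
          pr$stride_frequency_hz <-
            pr$stride_frequency_hz * (profile$f0_factor %||% 1)
          pr
        } else profile
        synth_walking(p, s$duration_s, rate, seg_seeds[i])
      },
      static = synth_static(s$duration_s, rate, seed = seg_seeds[i]),
      other = synth_other(s$duration_s, rate, seed = seg_seeds[i]),
      stop("unknown schedule label: ", s$label, call. = FALSE)
    )
  }
  n_per <- vapply(segs, function(x) length(x$recording$time_s), integer(1))
  offsets <- c(0L, cumsum(n_per))[seq_along(segs)]
  accel <- do.call(rbind, lapply(segs, function(x) x$recording$accel))
  gyro <- do.call(rbind, lapply(segs, function(x) x$recording$gyro))
  labels <- unlist(lapply(segs, `[[`, "labels"))
  truth <- unlist(lapply(segs, attr, "truth"))
  n <- nrow(accel)
  t <- (seq_len(n) - 1) / rate
  ev <- list(midswing = integer(0), heelstrike = integer(0))
  for (i in seq_along(segs)) {
    e <- attr(segs[[i]], "events")
    if (!is.null(e)) {
      ev$midswing <- c(ev$midswing, e$midswing + offsets[i])
      ev$heelstrike <- c(ev$heelstrike, e$heelstrike + offsets[i])
    }
  }
  meta <- recording_meta(subject_id, "proximal_shank", rate)
  out <- labeled_recording(imu_recording(t, accel, gyro, meta, "shank"),
                           labels)
  attr(out, "truth") <- truth
  attr(out, "events") <- ev
  out
}

#' Synthesize a cohort of subjects
#'
#' Each subject gets an independent seed derived from the master seed and an
#' individual gait profile perturbation (mid-swing amplitude +/- 20%, stride
#' frequency +/- 10%) so participants differ systematically, as real cohorts
#' do.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param schedule Schedule template (see [default_schedule()]).
#' @param seed Master seed; the full cohort is reproducible from it.
#' @param rate Sampling rate (Hz).
#' @param walking_speed_mps Base walking speed.
#' @return List of subjects; each element has `recording`
#'   (a [labeled_recording()] with `truth`/`events` attributes),
#'   `subject_id`, and the perturbation factors.
#' @export
synth_cohort <- function(n_subjects, schedule = default_schedule("three_class"),
                         seed = 1, rate = 100, walking_speed_mps = 1.0) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  amp_f <- stats::runif(n_subjects, 0.8, 1.2)
  f0_f <- stats::runif(n_subjects, 0.9, 1.1)
  lapply(seq_len(n_subjects), function(s) {
    prof <- gait_profile(walking_speed_mps)
    prof$amp_factor <- amp_f[s]
    prof$f0_factor <- f0_f[s]
    sid <- sprintf("S%02d", s)
    rec <- synth_recording(schedule, prof, rate, subj_seeds[s], sid)
    list(recording = rec, subject_id = sid,
         amp_factor = amp_f[s], f0_factor = f0_f[s])
  })
}
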