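#' Default run configuration
#'
#' Returns the full pipeline configuration with defaults matching the
#' published analysis: 5-second windows with 50% overlap at 100 Hz, a
#' 1 m/s^2 RMS gate for static windows, 500-sample edge trimming, the
#' harmonic gait detector on the mediolateral gyroscope (10 s windows,
#' prominence 5 deg/s, 50 deg/s rest threshold, 2 of the first 4 harmonics),
#' and the classifier/training hyperparameters (32 2x2 kernels, stride 2
#' ResNet block, 0.5 dropout, Adam, batch 64, early stopping patience 10).
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  cfg <- list(
    preprocess = list(
      window_seconds = 5,
      overlap_fraction = 0.5,
      target_rate_hz = 100,
      static_rms_limit_mps2 = 1.0,
      edge_trim_samples = 500
    ),
    labels = list(
      # PAMAP2 activity ID -> harmonized class ("drop" removes the activity)
      pamap2_map = list(
        `0` = "drop",          # transient between activities
        `1` = "static",        # lying
        `2` = "static",        # sitting
        `3` = "static",        # standing
        `4` = "walking",
        `5` = "running",
        `6` = "cycling",
        `7` = "drop",          # Nordic walking
        `12` = "stair_ascent",
        `13` = "stair_descent",
        `16` = "other",        # vacuum cleaning
        `17` = "other",        # ironing
        `24` = "drop"          # rope jumping
      )
    ),
    freq_gait = list(
      window_seconds = 10,
      hop_seconds = 5,
      rest_threshold = 50,
      n_harmonics = 4L,
      min_peaks = 2L,
      peak_prominence = 5,
      locomotor_band_hz = c(0.5, 3.0),
      harmonic_tolerance = 0.15,
      signal = "ml_gyro"
    ),
    model = list(
      window_sz = 500L,
      n_channels = 6L,
      n_classes = 7L,
      conv_filters = 32L,
      conv_kernel = c(2L, 2L),
      conv1_stride = 2L,
      conv2_stride = 1L,
      shortcut_stride = 2L,
      dropout_rate = 0.5,
      bilstm_units_per_direction = 64L,
      seed = 1L
    ),
    training = list(
      batch_size = 64L,
      max_epochs = 80L,
      early_stopping_patience = 10L,
      optimizer = "adam",
      loss = "sparse_categorical_crossentropy",
      learning_rate = 1e-3,
      monitor = "val_loss",
      seed = 1L
    ),
    stride = list(
      midswing_min_height_dps = 50,
      midswing_min_separation_s = 0.5,
      stride_duration_range_s = c(0.4, 4.0)
    ),
    bout = list(
      min_duration_s = 0
    )
  )
  structure(cfg, class = "run_config")
}

validate_config <- function(cfg) {
  p <- cfg$preprocess
  stopifnot(p$window_seconds > 0,
            p$overlap_fraction >= 0, p$overlap_fraction < 1,
            p$target_rate_hz > 0,
            p$static_rms_limit_mps2 > 0)
  f <- cfg$freq_gait
  stopifnot(f$min_peaks <= f$n_harmonics,
            f$locomotor_band_hz[1] < f$locomotor_band_hz[2])
  m <- cfg$model
  if (m$conv1_stride != m$shortcut_stride) {
    stop("conv1_stride must equal shortcut_stride (residual add shapes)",
         call. = FALSE)
  }
  stopifnot(m$dropout_rate >= 0, m$dropout_rate < 1,
            m$conv1_stride >= 1, m$conv2_stride >= 1)
  t <- cfg$training
  stopifnot(t$early_stopping_patience < t$max_epochs)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()], so partial files
#' only need to list the values they change. The result round-trips
#' losslessly through [write_config()].
#'
#' @param path Path to a YAML config file, or `NULL` for the defaults.
#' @return A `run_config` object.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  # yaml collapses length-2 numeric vectors fine, but integers may come back
  # as doubles; normalize the fields downstream code treats as integer
  for (f in c("window_sz", "n_channels", "n_classes", "conv_filters",
              "conv1_stride", "conv2_stride", "shortcut_stride",
              "bilstm_units_per_direction", "seed")) {
    cfg$model[[f]] <- as.integer(cfg$model[[f]])
  }
  cfg$model$conv_kernel <- as.integer(cfg$model$conv_kernel)
  for (f in c("batch_size", "max_epochs", "early_stopping_patience", "seed")) {
    cfg$training[[f]] <- as.integer(cfg$training[[f]])
  }
  cfg$freq_gait$n_harmonics <- as.integer(cfg$freq_gait$n_harmonics)
  cfg$freq_gait$min_peaks <- as.integer(cfg$freq_gait$min_peaks)
  validate_config(cfg)
  cfg
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param cfg A `run_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  windows: %gs, %.0f%% overlap @ %g Hz; static RMS < %g m/s^2\n",
              x$preprocess$window_seconds, 100 * x$preprocess$overlap_fraction,
              x$preprocess$target_rate_hz, x$preprocess$static_rms_limit_mps2))
  cat(sprintf("  freq detector: %gs windows, prominence %g, rest %g deg/s, %d/%d harmonics\n",
              x$freq_gait$window_seconds, x$freq_gait$peak_prominence,
              x$freq_gait$rest_threshold, x$freq_gait$min_peaks,
              x$freq_gait$n_harmonics))
  cat(sprintf("  model: window_sz %d, %d filters, BiLSTM %d/dir, dropout %g\n",
              x$model$window_sz, x$model$conv_filters,
              x$model$bilstm_units_per_direction, x$model$dropout_rate))
  invisible(x)
}
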