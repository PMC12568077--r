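# Independent oracles and small fixture builders shared across test files.

# Brute-force per-sample window-coverage vote: for each sample, count the
# windows covering it and the covering windows predicted walking.
brute_force_mask <- function(starts0, window_sz, is_walk, n_samples) {
  out <- logical(n_samples)
  for (i in seq_len(n_samples)) {
    cover <- 0L; votes <- 0L
    for (w in seq_along(starts0)) {
      s <- starts0[w] + 1L
      e <- s + window_sz - 1L
      if (i >= s && i <= e && s <= n_samples) {
        cover <- cover + 1L
        if (is_walk[w]) votes <- votes + 1L
      }
    }
    out[i] <- cover > 0L && votes > cover / 2
  }
  out
}

# Enumeration oracle for the sliding-window count: scan every candidate start
# and admit it when the whole window sits inside one non-"unlabeled" run and
# the start is hop-aligned with that run's start.
enumerate_window_starts <- function(labels, wsz, hop) {
  n <- length(labels)
  r <- rle(labels)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  run_of <- rep(seq_along(r$values), r$lengths)
  keep <- integer(0)
  if (n < wsz) return(keep)
  for (s in 1:(n - wsz + 1L)) {
    e <- s + wsz - 1L
    ri <- run_of[s]
    if (r$values[ri] == "unlabeled") next
    if (run_of[e] != ri) next
    if ((s - run_start[ri]) %% hop != 0L) next
    keep <- c(keep, s)
  }
  keep
}

# Literal transcription of the Wilson score closed form.
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  c(max(0, lo), min(1, hi))
}

# Write a synthetic PAMAP2-format protocol file: 54 space-separated columns,
# activity IDs and ankle accel/gyro planted per row. Values default to a
# quiet-standing pattern; accel in m/s^2, gyro in rad/s.
write_fake_pamap2 <- function(path, ids, accel = NULL, gyro = NULL,
                              na_rows = integer(0), na_col = 39L,
                              n_cols = 54L) {
  n <- length(ids)
  m <- matrix(0.1, n, n_cols)
  m[, 1] <- seq(0, by = 0.01, length.out = n)
  m[, 2] <- ids
  if (is.null(accel)) accel <- cbind(rep(9.81, n), 0, 0)
  if (is.null(gyro)) gyro <- matrix(0, n, 3)
  m[, 39:41] <- accel
  m[, 45:47] <- gyro
  if (length(na_rows) > 0) m[na_rows, na_col] <- NA
  lines <- apply(m, 1, function(r) paste(ifelse(is.na(r), "NaN",
                                                format(r, digits = 10)),
                                         collapse = " "))
  writeLines(lines, path)
  path
}

# Minimal generic IMU CSV.
write_fake_imu_csv <- function(path, time_s, accel, gyro, label) {
  d <- data.frame(time_s = time_s, ax = accel[, 1], ay = accel[, 2],
                  az = accel[, 3], gx = gyro[, 1], gy = gyro[, 2],
                  gz = gyro[, 3], label = label)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

# Small-model config used by classifier tests: 2 s windows at 50 Hz keep the
# recurrent sequence short enough for quick CPU training.
small_model_cfg <- function(n_classes = 3L, window_sz = 100L, units = 32L,
                            seed = 7L) {
  mcfg <- default_config()$model
  mcfg$window_sz <- as.integer(window_sz)
  mcfg$n_classes <- as.integer(n_classes)
  mcfg$bilstm_units_per_direction <- as.integer(units)
  mcfg$seed <- as.integer(seed)
  mcfg
}

small_preprocess_cfg <- function() {
  cfg <- default_config()
  cfg$preprocess$window_seconds <- 2
  cfg$preprocess$target_rate_hz <- 50
  cfg
}
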