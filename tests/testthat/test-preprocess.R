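make_rec <- function(accel, gyro, rate = 100, frame = "raw") {
  n <- nrow(accel)
  imu_recording((seq_len(n) - 1) / rate, accel, gyro,
                recording_meta("t", sampling_rate_hz = rate), frame)
}

test_that("calibration levels gravity and is rigid", {
  set.seed(1)
  rate <- 100
  n_st <- 3 * rate
  n_wk <- 6 * rate
  # gravity along sensor +x during standing; walking oscillation on raw y
  st_acc <- cbind(9.81, 0, 0)[rep(1, n_st), ] +
    matrix(rnorm(3 * n_st, 0, 0.02), n_st, 3)
  t <- (seq_len(n_wk) - 1) / rate
  osc <- 2 * sin(2 * pi * 1 * t) + 0.8 * pmax(sin(2 * pi * 1 * t), 0)^2
  wk_acc <- cbind(9.81, osc, 0.3 * sin(2 * pi * 2 * t))
  accel <- rbind(st_acc, wk_acc)
  gyro <- matrix(rnorm(3 * (n_st + n_wk), 0, 5), n_st + n_wk, 3)
  rec <- make_rec(accel, gyro)

  cal <- calibrate_to_shank_frame(rec, c(1, n_st), c(n_st + 1, n_st + n_wk))
  R <- attr(cal, "rotation")

  # orthonormal within 1e-12, norms preserved within 1e-9
  expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
  expect_lt(max(abs(sqrt(rowSums(cal$accel^2)) - sqrt(rowSums(rec$accel^2)))),
            1e-9)

  # standing gravity maps onto +z
  g_cal <- colMeans(cal$accel[1:n_st, ])
  expect_equal(g_cal[3], sqrt(sum(colMeans(st_acc)^2)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_lt(max(abs(g_cal[1:2])), 1e-9)

  # walking oscillation lands on the anteroposterior axis, positively skewed
  ap <- cal$accel[(n_st + 1):(n_st + n_wk), 1]
  expect_gt(stats::var(ap), stats::var(cal$accel[(n_st + 1):(n_st + n_wk), 2]))
  ap_c <- ap - mean(ap)
  expect_gt(mean(ap_c^3), 0)
})

test_that("calibration of an already-aligned recording is near identity", {
  set.seed(2)
  rate <- 100
  n_st <- 2 * rate; n_wk <- 5 * rate
  t <- (seq_len(n_wk) - 1) / rate
  osc <- 2 * sin(2 * pi * 1 * t) + 0.8 * pmax(sin(2 * pi * 1 * t), 0)^2
  accel <- rbind(cbind(0, 0, 9.81)[rep(1, n_st), ],
                 cbind(osc, 0.2 * sin(2 * pi * 2 * t), 9.81))
  accel <- accel + matrix(rnorm(3 * (n_st + n_wk), 0, 0.01), n_st + n_wk, 3)
  rec <- make_rec(accel, matrix(0, n_st + n_wk, 3))
  cal <- calibrate_to_shank_frame(rec, c(1, n_st), c(n_st + 1, n_st + n_wk))
  R <- attr(cal, "rotation")
  angle <- acos(pmin(1, (sum(diag(R)) - 1) / 2)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("calibration rejects a non-quiet standing interval", {
  set.seed(3)
  rate <- 100
  n <- 8 * rate
  t <- (seq_len(n) - 1) / rate
  accel <- cbind(9.81 + 3 * sin(2 * pi * 2 * t), 0, 0)
  rec <- make_rec(accel, matrix(0, n, 3))
  expect_error(calibrate_to_shank_frame(rec, c(1, 2 * rate), c(201, n)),
               "not quiet")
})

test_that("downsampling keeps passband amplitude and suppresses aliases", {
  rate <- 1600
  n <- 16000
  t <- (seq_len(n) - 1) / rate
  sig <- sin(2 * pi * 1 * t)
  alias <- 0.5 * sin(2 * pi * 700 * t)
  rec <- make_rec(cbind(sig + alias, 0, 9.81 + 0 * t),
                  cbind(sig, 0, 0), rate = rate)
  out <- downsample(rec, 100)
  expect_equal(length(out$time_s), 1000)
  expect_equal(out$meta$sampling_rate_hz, 100)

  # 1 Hz amplitude preserved within 1%
  x <- out$accel[, 1]
  f <- stats::fft(x - mean(x))
  amp <- 2 * Mod(f) / length(x)
  half <- amp[1:501]                           # one-sided spectrum
  i1 <- which.max(half[-1]) + 1L
  expect_equal((i1 - 1) * 100 / 1000, 1)       # located at 1 Hz
  expect_equal(half[i1], 1, tolerance = 0.01)
  # 700 Hz component aliases into the passband: residual power < 1%
  alias_bin <- half[-c(1, i1 - 1, i1, i1 + 1)]
  expect_lt(max(alias_bin^2) / 1^2, 0.01)

  expect_error(downsample(rec, 300), "integer multiple")
})

test_that("label harmonization follows the mapping and flags unmapped labels", {
  rec <- make_rec(matrix(9.81, 6, 3), matrix(0, 6, 3))
  lr <- labeled_recording(rec, c("lying", "sitting", "standing",
                                 "vacuuming", "rope_jumping", "walk"))
  mapping <- list(lying = "static", sitting = "static", standing = "static",
                  vacuuming = "other", rope_jumping = "drop",
                  walk = "walking")
  out <- harmonize_labels(lr, mapping)
  expect_equal(out$labels,
               c("static", "static", "static", "other", "unlabeled",
                 "walking"))
  expect_error(harmonize_labels(lr, mapping[-6]), "walk")
})

test_that("edge trimming removes transition samples and short runs", {
  rec <- make_rec(matrix(9.81, 4900, 3), matrix(0, 4900, 3))
  lr <- labeled_recording(rec, c(rep("walking", 1500), rep("static", 900),
                                 rep("walking", 2000), rep("other", 500)))
  out <- trim_activity_edges(lr, 500L)
  expect_equal(sum(out$labels == "walking"),
               500 + 1000)               # 1500-run keeps 500, 2000-run keeps 1000
  expect_equal(which(out$labels == "walking")[1], 501)
  expect_equal(sum(out$labels == "static"), 0)   # 900 <= 1000, fully removed
  expect_equal(sum(out$labels == "other"), 0)    # 500-run fully removed
  # retained block of the first run is exactly samples 501..1000
  expect_true(all(out$labels[501:1000] == "walking"))
})

test_that("window segmentation counts match the arithmetic and the oracle", {
  cfg <- default_config()
  rec <- make_rec(matrix(9.81, 1000, 3), matrix(0, 1000, 3))
  lr <- labeled_recording(rec, rep("walking", 1000))
  ws <- segment_windows(lr, cfg)
  expect_equal(dim(ws$windows)[1], 3)          # floor((1000-500)/250)+1
  expect_equal(ws$starts, c(0L, 250L, 500L))

  lr2 <- labeled_recording(make_rec(matrix(9.81, 499, 3), matrix(0, 499, 3)),
                           rep("walking", 499))
  expect_equal(dim(segment_windows(lr2, cfg)$windows)[1], 0)
})

test_that("windows never span label boundaries (randomized, oracle-checked)", {
  set.seed(42)
  cfg <- default_config()
  cfg$preprocess$window_seconds <- 0.5   # wsz 50 at 100 Hz, hop 25
  for (rep_i in 1:50) {
    n_runs <- sample(2:6, 1)
    lens <- sample(20:200, n_runs, replace = TRUE)
    labs <- sample(c("walking", "static", "other", "unlabeled"), n_runs,
                   replace = TRUE)
    labels <- rep(labs, lens)
    n <- length(labels)
    rec <- make_rec(matrix(9.81, n, 3), matrix(0, n, 3))
    ws <- segment_windows(labeled_recording(rec, labels), cfg)
    oracle <- enumerate_window_starts(labels, 50L, 25L)
    expect_equal(sort(ws$starts), sort(oracle - 1L))
    if (length(ws$starts) > 0) {
      for (k in seq_along(ws$starts)) {
        idx <- (ws$starts[k] + 1):(ws$starts[k] + 50)
        expect_equal(length(unique(labels[idx])), 1)
        expect_false("unlabeled" %in% labels[idx])
      }
    }
  }
})

test_that("static RMS gate keeps still windows and removes jostled ones", {
  rate <- 100
  wsz <- 500
  t <- (seq_len(wsz) - 1) / rate
  still <- cbind(0, 0, rep(9.81, wsz))
  # sinusoidal jostle along gravity with RMS 2: amplitude 2*sqrt(2)
  jostle <- cbind(0, 0, 9.81 + 2 * sqrt(2) * sin(2 * pi * 4 * t))
  # boundary case: alternating +/-1 deviation -> RMS 1 (nudged up 1e-12 so
  # the computed RMS cannot round below the strict "< 1" gate)
  boundary <- cbind(0, 0, 9.81 + rep(c(1, -1), wsz / 2) * (1 + 1e-12))
  arr <- array(0, dim = c(3, wsz, 6))
  arr[1, , 1:3] <- still
  arr[2, , 1:3] <- jostle
  arr[3, , 1:3] <- boundary
  ws <- window_set(arr, rep("static", 3), c(0L, 500L, 1000L), wsz, rate)
  out <- filter_static_windows(ws, 1.0)
  expect_equal(dim(out$windows)[1], 1)
  expect_equal(out$starts, 0L)

  # non-static windows untouched regardless of motion
  ws2 <- window_set(arr, rep("walking", 3), c(0L, 500L, 1000L), wsz, rate)
  expect_equal(dim(filter_static_windows(ws2, 1.0)$windows)[1], 3)
})

test_that("participant scaler standardizes walking samples per channel", {
  set.seed(7)
  n <- 2000
  rec <- make_rec(matrix(rnorm(3 * n, 5, 2), n, 3),
                  matrix(rnorm(3 * n, -10, 30), n, 3))
  lr <- labeled_recording(rec, rep(c("walking", "static"), each = n / 2))
  sc <- fit_participant_scaler(lr)
  wi <- 1:(n / 2)
  sig <- cbind(rec$accel, rec$gyro)[wi, ]
  scaled <- sweep(sweep(sig, 2, sc$mean), 2, sc$sd, "/")
  expect_lt(max(abs(colMeans(scaled))), 1e-6)
  expect_lt(max(abs(apply(scaled, 2, sd) - 1)), 1e-6)

  # degenerate channel guard: constant channel unchanged
  rec2 <- make_rec(cbind(rep(1, n), rnorm(n), rnorm(n)),
                   matrix(rnorm(3 * n), n, 3))
  lr2 <- labeled_recording(rec2, rep("walking", n))
  sc2 <- fit_participant_scaler(lr2)
  expect_equal(sc2$sd[[1]], 1)

  lr3 <- labeled_recording(rec, rep("static", n))
  expect_error(fit_participant_scaler(lr3), "walking section")
})

test_that("two participants with different gains standardize independently", {
  set.seed(8)
  n <- 1000
  mk <- function(gain) {
    rec <- make_rec(matrix(rnorm(3 * n, 0, gain), n, 3),
                    matrix(rnorm(3 * n, 0, gain * 10), n, 3))
    labeled_recording(rec, rep("walking", n))
  }
  a <- mk(1); b <- mk(4)
  sa <- fit_participant_scaler(a); sb <- fit_participant_scaler(b)
  expect_gt(sb$sd[[1]] / sa$sd[[1]], 2)
  # after own-scaler application each pools to unit spread
  wsa <- apply_scaler(segment_windows(a, {
    cfg <- default_config(); cfg$preprocess$window_seconds <- 1; cfg
  }), sa)
  expect_equal(sd(as.vector(wsa$windows[, , 1])), 1, tolerance = 0.05)
})

test_that("the window pipeline is deterministic", {
  cohort <- synth_cohort(2, default_schedule("three_class"), seed = 5)
  cfg <- small_preprocess_cfg()
  w1 <- cohort_windows(cohort, cfg)
  w2 <- cohort_windows(synth_cohort(2, default_schedule("three_class"),
                                    seed = 5), cfg)
  expect_identical(w1$windows, w2$windows)
  expect_identical(w1$labels, w2$labels)
})
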