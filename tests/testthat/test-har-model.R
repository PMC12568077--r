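test_that("shape propagation matches the architecture arithmetic", {
  sh <- har_shapes(default_config()$model)
  expect_equal(sh$post_resnet, c(250L, 3L, 32L))
  expect_equal(sh$flatten_len, 24000L)
  expect_equal(sh$seq_steps, 250L)
  expect_equal(sh$seq_features, 96L)

  # verified against a forward pass on a small config
  mcfg <- small_model_cfg(window_sz = 20L, units = 4L)
  m <- har_build(mcfg)
  X <- array(rnorm(2 * 20 * 6), c(2, 20, 6))
  fw <- gaitbouts:::har_forward(m, X, training = FALSE, collect = TRUE)
  expect_equal(dim(fw$caches$added),
               c(2L, har_shapes(mcfg)$post_resnet))
  expect_equal(dim(fw$caches$seqX), c(2L, 10L, 96L))
})

test_that("output layer width equals the class count", {
  m <- har_build(small_model_cfg(n_classes = 7L, window_sz = 20L, units = 4L))
  expect_equal(ncol(m$params$dense_W), 7L)
})

test_that("invalid architectures are rejected", {
  mcfg <- small_model_cfg(window_sz = 21L)
  expect_error(har_build(mcfg), "divisible")
  mcfg2 <- small_model_cfg(window_sz = 24L)
  mcfg2$shortcut_stride <- 3L
  expect_error(har_build(mcfg2), "shortcut")
})

test_that("parameter count is a pure function of the configuration", {
  n1 <- har_n_params(har_build(small_model_cfg(seed = 1L)))
  n2 <- har_n_params(har_build(small_model_cfg(seed = 99L)))
  expect_identical(n1, n2)
  # regression: conv (160+4128+160) + bn (2*64) + bilstm + dense
  mcfg <- small_model_cfg()             # window 100, 6 ch, 3 classes, U=32
  U <- 32L; D <- 96L
  expected <- 160L + 4128L + 160L + 128L +
    2L * (D * 4L * U + U * 4L * U + 4L * U) + (2L * U * 3L + 3L)
  expect_identical(har_n_params(har_build(mcfg)), expected)
})

test_that("analytic gradients match finite differences", {
  mcfg <- small_model_cfg(n_classes = 3L, window_sz = 8L, units = 3L,
                          seed = 5L)
  mcfg$n_channels <- 4L
  mcfg$dropout_rate <- 0
  m <- har_build(mcfg)
  set.seed(9)
  X <- array(rnorm(6 * 8 * 4), c(6, 8, 4))
  y <- sample(1:3, 6, replace = TRUE)
  fw <- gaitbouts:::har_forward(m, X, training = TRUE, collect = TRUE)
  sx <- gaitbouts:::softmax_xent(fw$logits, y)
  g <- gaitbouts:::har_backward(m, fw, sx$dZ)
  loss_at <- function(mm) {
    f <- gaitbouts:::har_forward(mm, X, training = TRUE)
    gaitbouts:::softmax_xent(f$logits, y)$loss
  }
  eps <- 1e-5
  for (nm in names(g)) {
    p <- m$params[[nm]]
    idx <- sample(length(p), min(3, length(p)))
    for (i in idx) {
      m2 <- m; m2$params[[nm]][i] <- p[i] + eps
      m3 <- m; m3$params[[nm]][i] <- p[i] - eps
      num <- (loss_at(m2) - loss_at(m3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("softmax probabilities are valid and prediction is pure", {
  mcfg <- small_model_cfg(window_sz = 20L, units = 4L)
  m <- har_build(mcfg)
  m$class_levels <- c("static", "walking", "other")
  set.seed(3)
  arr <- array(rnorm(4 * 20 * 6), c(4, 20, 6))
  arr[4, , ] <- arr[1, , ]              # duplicate window
  ws <- window_set(arr, rep("static", 4), c(0L, 10L, 20L, 30L), 20L, 10)
  p <- predict(m, ws)
  expect_equal(rowSums(p$probabilities), rep(1, 4), tolerance = 1e-5)
  expect_equal(p$probabilities[4, ], p$probabilities[1, ])
  expect_true(all(p$predicted_labels %in% m$class_levels))

  ws_bad <- window_set(array(0, c(1, 10, 6)), "static", 0L, 10L, 10)
  expect_error(predict(m, ws_bad), "mismatch")
})

synth_training_fixture <- function(n_per_class = 24, seed = 33) {
  # well-separated tiny 2-class problem: static vs walking windows, scaled
  cohort <- synth_cohort(2, list(
    list(label = "static", duration_s = 26),
    list(label = "walking", duration_s = 26, speed = 1.0)), seed = seed,
    rate = 100)
  cfg <- small_preprocess_cfg()
  ws <- cohort_windows(cohort, cfg)
  ws
}

test_that("training learns a separable problem and early stopping obeys patience", {
  ws <- synth_training_fixture()
  ids <- attr(ws, "subjects")
  tr <- subset_windows(ws, ids[1])
  va <- subset_windows(ws, ids[2])
  tcfg <- default_config()$training
  tcfg$max_epochs <- 6L
  tcfg$early_stopping_patience <- 3L
  tcfg$batch_size <- 16L
  tcfg$seed <- 11L
  m <- har_train(har_build(small_model_cfg(n_classes = 2L)), tr, va, tcfg)
  expect_true(m$trained)
  h <- m$history
  expect_equal(m$best_epoch, which.min(h$val_loss))
  expect_lte(nrow(h) - m$best_epoch, tcfg$early_stopping_patience)
  # training loss decreases over the first epochs on this separable fixture
  expect_lt(h$loss[3], h$loss[1])
  # converged model separates its own training windows
  p <- predict(m, tr)
  expect_gte(mean(p$predicted_labels == tr$labels), 0.98)
})

test_that("training is deterministic under fixed seeds", {
  ws <- synth_training_fixture()
  ids <- attr(ws, "subjects")
  tr <- subset_windows(ws, ids[1])
  va <- subset_windows(ws, ids[2])
  tcfg <- default_config()$training
  tcfg$max_epochs <- 2L
  tcfg$early_stopping_patience <- 1L
  tcfg$batch_size <- 16L
  tcfg$seed <- 21L
  run <- function() {
    har_train(har_build(small_model_cfg(n_classes = 2L, seed = 13L)),
              tr, va, tcfg)$history
  }
  expect_identical(run(), run())
})

test_that("training guards: empty set, single class, shared participants", {
  ws <- synth_training_fixture()
  ids <- attr(ws, "subjects")
  tr <- subset_windows(ws, ids[1])
  va <- subset_windows(ws, ids[2])
  empty <- subset_windows(ws, character(0))
  tcfg <- default_config()$training
  tcfg$max_epochs <- 2L; tcfg$early_stopping_patience <- 1L; tcfg$seed <- 1L
  expect_error(har_train(har_build(small_model_cfg(n_classes = 2L)),
                         empty, va, tcfg), "empty training set")
  expect_error(har_train(har_build(small_model_cfg(n_classes = 2L)),
                         tr, tr, tcfg), "share participants")

  static_only <- ws
  keep <- ws$labels == "static" & attr(ws, "window_subject") == ids[1]
  so <- window_set(ws$windows[keep, , , drop = FALSE], ws$labels[keep],
                   ws$starts[keep], ws$window_sz, ws$sampling_rate_hz)
  expect_warning(
    har_train(har_build(small_model_cfg(n_classes = 2L)), so, va, tcfg),
    "single class")
})

test_that("adversarial fixture: strictly worsening validation stops at 1 + patience", {
  # training and validation drawn from different distributions so val loss
  # rises from the start
  set.seed(4)
  mcfg <- small_model_cfg(n_classes = 2L, window_sz = 20L, units = 4L)
  mk <- function(mu) {
    arr <- array(rnorm(40 * 20 * 6, mu), c(40, 20, 6))
    lab <- rep(c("static", "walking"), 20)
    # make train separable by channel mean, val anti-correlated
    for (i in seq_len(40)) arr[i, , 1] <- arr[i, , 1] +
        ifelse(lab[i] == "walking", mu, -mu)
    window_set(arr, lab, seq(0L, by = 10L, length.out = 40), 20L, 10)
  }
  tr <- mk(2)
  va <- mk(-2)                          # opposite association
  tcfg <- default_config()$training
  tcfg$max_epochs <- 20L
  tcfg$early_stopping_patience <- 3L
  tcfg$batch_size <- 20L
  tcfg$seed <- 2L
  m <- har_train(har_build(mcfg), tr, va, tcfg)
  h <- m$history
  if (all(diff(h$val_loss) > 0)) {
    expect_equal(nrow(h), 1L + tcfg$early_stopping_patience)
    expect_equal(m$best_epoch, 1L)
  } else {
    expect_lte(nrow(h) - m$best_epoch, tcfg$early_stopping_patience)
  }
})

test_that("model save/load round-trips", {
  m <- har_build(small_model_cfg(window_sz = 20L, units = 4L))
  f <- tempfile(fileext = ".rds")
  save_har_model(m, f)
  m2 <- load_har_model(f)
  expect_identical(m2$params, m$params)
  saveRDS(1:3, f)
  expect_error(load_har_model(f), "not a har_model")
})
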