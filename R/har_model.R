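#' Residual-convolutional + bidirectional LSTM activity classifier
#'
#' Constructs the untrained classifier. The layer graph is: input
#' `(window_sz, n_channels, 1)` -> conv(32 kernels, 2x2, stride 2, same
#' padding) -> batch norm -> ReLU -> conv(32, 2x2, stride 1, same) -> batch
#' norm, with a convolutional shortcut (32, 2x2, stride 2, same) from the
#' input added to the main branch -> ReLU -> dropout 0.5 -> flatten ->
#' reshape to a sequence of `window_sz/2` steps x `(n_channels/2) * 32`
#' features -> bidirectional LSTM -> dropout 0.5 -> dense(n_classes) ->
#' softmax. The sequence reshape preserves the temporal axis so the
#' recurrent block sees the windows in time order.
#'
#' @param cfg Model configuration block (see [default_config()]`$model`).
#' @return An object of class `har_model` (untrained).
#' @export
har_build <- function(cfg = default_config()$model) {
  if (cfg$window_sz %% cfg$conv1_stride != 0) {
    stop("window_sz must be divisible by conv1_stride", call. = FALSE)
  }
  if (cfg$conv1_stride != cfg$shortcut_stride) {
    stop("residual add requires conv1_stride == shortcut_stride ",
         "(main and shortcut output shapes must match)", call. = FALSE)
  }
  k <- cfg$conv_kernel
  Fn <- cfg$conv_filters
  U <- cfg$bilstm_units_per_direction
  sh <- har_shapes(cfg)
  D <- sh$seq_features
  K <- cfg$n_classes

  set.seed(cfg$seed)
  params <- list(
    conv1_W = glorot_uniform(c(k[1], k[2], 1L, Fn), k[1] * k[2], k[1] * k[2] * Fn),
    conv1_b = numeric(Fn),
    bn1_gamma = rep(1, Fn), bn1_beta = numeric(Fn),
    conv2_W = glorot_uniform(c(k[1], k[2], Fn, Fn), k[1] * k[2] * Fn,
                             k[1] * k[2] * Fn),
    conv2_b = numeric(Fn),
    bn2_gamma = rep(1, Fn), bn2_beta = numeric(Fn),
    sc_W = glorot_uniform(c(k[1], k[2], 1L, Fn), k[1] * k[2], k[1] * k[2] * Fn),
    sc_b = numeric(Fn),
    lstmf_Wx = glorot_uniform(c(D, 4L * U), D, 4L * U),
    lstmf_Wh = do.call(cbind, replicate(4, orthogonal_init(U, U),
                                        simplify = FALSE)),
    lstmf_b = c(numeric(U), rep(1, U), numeric(2L * U)),
    lstmb_Wx = glorot_uniform(c(D, 4L * U), D, 4L * U),
    lstmb_Wh = do.call(cbind, replicate(4, orthogonal_init(U, U),
                                        simplify = FALSE)),
    lstmb_b = c(numeric(U), rep(1, U), numeric(2L * U)),
    dense_W = glorot_uniform(c(2L * U, K), 2L * U, K),
    dense_b = numeric(K)
  )
  bn <- list(bn1_mean = numeric(Fn), bn1_var = rep(1, Fn),
             bn2_mean = numeric(Fn), bn2_var = rep(1, Fn))
  structure(list(cfg = cfg, params = params, bn = bn,
                 class_levels = NULL, history = NULL, best_epoch = NA_integer_,
                 trained = FALSE),
            class = "har_model")
}

#' Shape propagation through the classifier
#'
#' @param cfg Model configuration block.
#' @return List with `post_resnet` (steps, width, filters), `flatten_len`,
#'   `seq_steps`, `seq_features`.
#' @export
har_shapes <- function(cfg) {
  OH <- as.integer(ceiling(cfg$window_sz / cfg$conv1_stride))
  OW <- as.integer(ceiling(cfg$n_channels / cfg$conv1_stride))
  Fn <- cfg$conv_filters
  list(post_resnet = c(OH, OW, Fn),
       flatten_len = OH * OW * Fn,
       seq_steps = OH,
       seq_features = OW * Fn)
}

#' Number of trainable parameters
#' @param model A `har_model`.
#' @return Integer parameter count.
#' @export
har_n_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# Full forward pass. X3: (B, T, C) array. Returns logits; with
# collect = TRUE also returns every cache needed for backprop. Batch-norm
# running statistics are updated when training = TRUE.
har_forward <- function(model, X3, training = FALSE, collect = FALSE) {
  cfg <- model$cfg
  p <- model$params
  d <- dim(X3); B <- d[1]
  X <- X3; dim(X) <- c(d[1], d[2], d[3], 1L)
  s1 <- c(cfg$conv1_stride, cfg$conv1_stride)
  s2 <- c(cfg$conv2_stride, cfg$conv2_stride)

  c1 <- conv2d_forward(X, p$conv1_W, p$conv1_b, s1)
  b1 <- batchnorm_forward(c1$out, p$bn1_gamma, p$bn1_beta,
                          model$bn$bn1_mean, model$bn$bn1_var, training)
  r1 <- pmax(b1$out, 0)
  c2 <- conv2d_forward(r1, p$conv2_W, p$conv2_b, s2)
  b2 <- batchnorm_forward(c2$out, p$bn2_gamma, p$bn2_beta,
                          model$bn$bn2_mean, model$bn$bn2_var, training)
  sc <- conv2d_forward(X, p$sc_W, p$sc_b,
                       c(cfg$shortcut_stride, cfg$shortcut_stride))
  if (!identical(dim(b2$out), dim(sc$out))) {
    stop("residual add shape mismatch: main ",
         paste(dim(b2$out), collapse = "x"), " vs shortcut ",
         paste(dim(sc$out), collapse = "x"), call. = FALSE)
  }
  added <- b2$out + sc$out
  r2 <- pmax(added, 0)
  dr1 <- dropout_forward(r2, cfg$dropout_rate, training)

  sh <- dim(r2)  # (B, OH, OW, F)
  seqX <- dr1$out
  dim(seqX) <- c(B, sh[2], sh[3] * sh[4])

  lf <- lstm_forward(seqX, p$lstmf_Wx, p$lstmf_Wh, p$lstmf_b, reverse = FALSE)
  lb <- lstm_forward(seqX, p$lstmb_Wx, p$lstmb_Wh, p$lstmb_b, reverse = TRUE)
  H <- cbind(lf$h_last, lb$h_last)
  dr2 <- dropout_forward(H, cfg$dropout_rate, training)
  logits <- bc_add(dr2$out %*% p$dense_W, p$dense_b)

  out <- list(logits = logits,
              bn = list(bn1_mean = b1$run_mean, bn1_var = b1$run_var,
                        bn2_mean = b2$run_mean, bn2_var = b2$run_var))
  if (collect) {
    out$caches <- list(X = X, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                       sc = sc, added = added, mask1 = dr1$mask, seqX = seqX,
                       lf = lf, lb = lb, Hdrop = dr2$out, mask2 = dr2$mask,
                       sh = sh)
  }
  out
}

har_backward <- function(model, fw, dZ) {
  cfg <- model$cfg
  p <- model$params
  cc <- fw$caches
  g <- list()
  g$dense_W <- crossprod(cc$Hdrop, dZ)
  g$dense_b <- colSums(dZ)
  dH <- dZ %*% t(p$dense_W)
  if (!is.null(cc$mask2)) dH <- dH * cc$mask2
  U <- cfg$bilstm_units_per_direction
  dlf <- lstm_backward(dH[, seq_len(U), drop = FALSE], cc$seqX,
                       p$lstmf_Wx, p$lstmf_Wh, cc$lf)
  dlb <- lstm_backward(dH[, U + seq_len(U), drop = FALSE], cc$seqX,
                       p$lstmb_Wx, p$lstmb_Wh, cc$lb)
  g$lstmf_Wx <- dlf$dWx; g$lstmf_Wh <- dlf$dWh; g$lstmf_b <- dlf$db
  g$lstmb_Wx <- dlb$dWx; g$lstmb_Wh <- dlb$dWh; g$lstmb_b <- dlb$db
  dseq <- dlf$dX + dlb$dX
  dim(dseq) <- cc$sh
  if (!is.null(cc$mask1)) dseq <- dseq * cc$mask1
  dadd <- dseq * (cc$added > 0)

  dsc <- conv2d_backward(dadd, p$sc_W, cc$sc$cache)
  g$sc_W <- dsc$dW; g$sc_b <- dsc$db

  db2 <- batchnorm_backward(dadd, cc$b2$cache)
  g$bn2_gamma <- db2$dgamma; g$bn2_beta <- db2$dbeta
  dc2 <- conv2d_backward(db2$dx, p$conv2_W, cc$c2$cache)
  g$conv2_W <- dc2$dW; g$conv2_b <- dc2$db
  dr1 <- dc2$dX * (cc$r1 > 0)
  db1 <- batchnorm_backward(dr1, cc$b1$cache)
  g$bn1_gamma <- db1$dgamma; g$bn1_beta <- db1$dbeta
  dc1 <- conv2d_backward(db1$dx, p$conv1_W, cc$c1$cache)
  g$conv1_W <- dc1$dW; g$conv1_b <- dc1$db
  g
}

labels_to_index <- function(labels, levels) {
  idx <- match(labels, levels)
  if (anyNA(idx)) {
    stop("labels outside the model's class set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Train the activity classifier
#'
#' Minimises sparse categorical cross-entropy with Adam, monitoring
#' validation loss with early stopping: training halts when the validation
#' loss has not improved for `early_stopping_patience` consecutive epochs (or
#' at `max_epochs`), and the weights from the best-validation-loss epoch are
#' restored. Train and validation sets must come from disjoint participants;
#' when both window sets carry a `subject` attribute this is asserted.
#'
#' @param model An untrained (or trained) `har_model`.
#' @param train,val [window_set()]s with class labels.
#' @param tcfg Training configuration block (see [default_config()]`$training`).
#' @param class_levels Optional explicit class ordering; defaults to the
#'   harmonized taxonomy order restricted to labels present.
#' @param verbose Print one line per epoch.
#' @return The trained `har_model` with `history` (per-epoch data frame of
#'   `loss`, `val_loss`, `acc`, `val_acc`) and `best_epoch` filled in.
#' @export
har_train <- function(model, train, val, tcfg = default_config()$training,
                      class_levels = NULL, verbose = FALSE) {
  if (dim(train$windows)[1] == 0L) stop("empty training set", call. = FALSE)
  subj_tr <- attr(train, "subjects"); subj_va <- attr(val, "subjects")
  if (!is.null(subj_tr) && !is.null(subj_va) &&
      length(intersect(subj_tr, subj_va)) > 0) {
    stop("train and validation sets share participants: ",
         paste(intersect(subj_tr, subj_va), collapse = ", "), call. = FALSE)
  }
  if (is.null(class_levels)) {
    present <- unique(c(train$labels, val$labels))
    class_levels <- c(intersect(ACTIVITY_CLASSES, present),
                      setdiff(sort(present), ACTIVITY_CLASSES))
  }
  if (length(class_levels) > model$cfg$n_classes) {
    stop("more classes present than model n_classes", call. = FALSE)
  }
  if (length(unique(train$labels)) == 1L) {
    warning("training set contains a single class")
  }
  y_tr <- labels_to_index(train$labels, class_levels)
  y_va <- labels_to_index(val$labels, class_levels)
  Xtr <- train$windows
  Xva <- val$windows
  n <- dim(Xtr)[1]
  bs <- tcfg$batch_size

  set.seed(tcfg$seed)
  opt <- adam_init(model$params)
  best_val <- Inf
  best <- list(params = model$params, bn = model$bn, epoch = 0L)
  wait <- 0L
  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     val_loss = numeric(0), acc = numeric(0),
                     val_acc = numeric(0))

  for (epoch in seq_len(tcfg$max_epochs)) {
    idx <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (b0 in seq(1L, n, by = bs)) {
      bi <- idx[b0:min(b0 + bs - 1L, n)]
      Xb <- Xtr[bi, , , drop = FALSE]
      fw <- har_forward(model, Xb, training = TRUE, collect = TRUE)
      model$bn <- fw$bn
      sx <- softmax_xent(fw$logits, y_tr[bi])
      g <- har_backward(model, fw, sx$dZ)
      st <- adam_step(model$params, g, opt, lr = tcfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + sx$loss * length(bi)
      ep_correct <- ep_correct +
        sum(max.col(sx$P, ties.method = "first") == y_tr[bi])
    }
    ev <- har_evaluate(model, Xva, y_va)
    hist <- rbind(hist, data.frame(
      epoch = epoch, loss = ep_loss / n, val_loss = ev$loss,
      acc = ep_correct / n, val_acc = ev$acc))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.4f acc %.3f  val_loss %.4f val_acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, ev$loss, ev$acc))
    }
    if (ev$loss < best_val - 1e-12) {
      best_val <- ev$loss
      best <- list(params = model$params, bn = model$bn, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tcfg$early_stopping_patience) break
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  model$best_epoch <- best$epoch
  model$class_levels <- class_levels
  model$history <- hist
  model$trained <- TRUE
  model
}

# chunked inference loss/accuracy
har_evaluate <- function(model, X, y, chunk = 256L) {
  n <- dim(X)[1]
  loss <- 0; correct <- 0L
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    fw <- har_forward(model, X[bi, , , drop = FALSE], training = FALSE)
    sx <- softmax_xent(fw$logits, y[bi])
    loss <- loss + sx$loss * length(bi)
    correct <- correct + sum(max.col(sx$P, ties.method = "first") == y[bi])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict window activities
#'
#' Runs the classifier in inference mode (dropout disabled, batch-norm using
#' running statistics) and returns per-window class probabilities and argmax
#' labels (ties broken toward the lowest class index).
#'
#' @param object A trained `har_model`.
#' @param ws A [window_set()] with matching `window_sz` and channel count.
#' @param ... Unused.
#' @return An object of class `prediction_set`: fields `probabilities`
#'   (W x n_classes), `predicted_labels`, `starts`, `window_sz`,
#'   `class_levels`.
#' @export
predict.har_model <- function(object, ws, ...) {
  if (ws$window_sz != object$cfg$window_sz ||
      ws$n_channels != object$cfg$n_channels) {
    stop(sprintf("window shape mismatch: model expects %d x %d, got %d x %d",
                 object$cfg$window_sz, object$cfg$n_channels,
                 ws$window_sz, ws$n_channels), call. = FALSE)
  }
  if (is.null(object$class_levels)) stop("model is untrained", call. = FALSE)
  X <- ws$windows
  n <- dim(X)[1]
  K <- length(object$class_levels)
  P <- matrix(0, n, K, dimnames = list(NULL, object$class_levels))
  for (b0 in seq(1L, n, by = 256L)) {
    bi <- b0:min(b0 + 255L, n)
    fw <- har_forward(object, X[bi, , , drop = FALSE], training = FALSE)
    P[bi, ] <- softmax_rows(fw$logits)[, seq_len(K)]
  }
  # renormalise over the classes actually in use (dense width may exceed K)
  P <- P / rowSums(P)
  structure(list(probabilities = P,
                 predicted_labels = object$class_levels[
                   max.col(P, ties.method = "first")],
                 starts = ws$starts, window_sz = ws$window_sz,
                 sampling_rate_hz = ws$sampling_rate_hz,
                 class_levels = object$class_levels),
            class = "prediction_set")
}

#' @export
print.har_model <- function(x, ...) {
  sh <- har_shapes(x$cfg)
  cat(sprintf("<har_model> %s, %d classes, %s parameters\n",
              if (x$trained) "trained" else "untrained",
              x$cfg$n_classes, format(har_n_params(x), big.mark = ",")))
  cat(sprintf("  input (%d, %d, 1) -> resnet (%d, %d, %d) -> seq %d x %d -> BiLSTM %d/dir -> dense %d\n",
              x$cfg$window_sz, x$cfg$n_channels,
              sh$post_resnet[1], sh$post_resnet[2], sh$post_resnet[3],
              sh$seq_steps, sh$seq_features,
              x$cfg$bilstm_units_per_direction, x$cfg$n_classes))
  if (x$trained) {
    cat(sprintf("  best epoch %d of %d (val_loss %.4f, val_acc %.3f)\n",
                x$best_epoch, nrow(x$history),
                x$history$val_loss[x$best_epoch],
                x$history$val_acc[x$best_epoch]))
  }
  invisible(x)
}

#' @export
summary.har_model <- function(object, ...) {
  print(object)
  if (object$trained) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' @export
print.prediction_set <- function(x, ...) {
  cat(sprintf("<prediction_set> %d windows, classes: %s\n",
              nrow(x$probabilities), paste(x$class_levels, collapse = ", ")))
  invisible(x)
}

#' Save / load a trained model
#'
#' Serializes the full model object (architecture config, weights, running
#' statistics, class mapping, history) with R's native serialization.
#'
#' @param model A `har_model`.
#' @param path File path (conventionally `.rds`).
#' @return `path` invisibly (save); the model (load).
#' @export
save_har_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_har_model
#' @export
load_har_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "har_model")) stop("not a har_model file", call. = FALSE)
  m
}
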