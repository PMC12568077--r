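# High-level orchestration shared by the CLI and the test/evaluation code.

#' Preprocess one labeled recording into scaled model windows
#'
#' Runs the window-preparation chain: (optional) downsampling to the
#' configured target rate, edge trimming, segmentation into sliding windows,
#' the static-window RMS gate, and participant-specific scaling fitted on the
#' recording's walking samples.
#'
#' @param lrec A [labeled_recording()] with harmonized labels.
#' @param cfg A `run_config`.
#' @param trim Apply [trim_activity_edges()]? (Edge trimming is meant for
#'   datasets with taped activity transitions; synthetic recordings don't
#'   need it.)
#' @return A [window_set()], scaled; the scaler is attached as attribute
#'   `"scaler"`.
#' @export
prepare_windows <- function(lrec, cfg = default_config(), trim = FALSE) {
  rate <- lrec$recording$meta$sampling_rate_hz
  if (rate != cfg$preprocess$target_rate_hz) {
    lrec <- downsample_labeled(lrec, cfg$preprocess$target_rate_hz)
  }
  if (trim) lrec <- trim_activity_edges(lrec, cfg$preprocess$edge_trim_samples)
  ws <- segment_windows(lrec, cfg)
  ws <- filter_static_windows(ws, cfg$preprocess$static_rms_limit_mps2)
  sc <- fit_participant_scaler(lrec)
  out <- apply_scaler(ws, sc)
  attr(out, "scaler") <- sc
  out
}

#' Build pooled window sets for a synthetic cohort
#'
#' Applies [prepare_windows()] per subject and concatenates the results,
#' recording each window's subject so subject-disjoint splits can be
#' asserted.
#'
#' @param cohort Output of [synth_cohort()].
#' @param cfg A `run_config`.
#' @return A [window_set()] with attributes `subjects` (unique ids) and
#'   `window_subject` (per-window id).
#' @export
cohort_windows <- function(cohort, cfg = default_config()) {
  sets <- lapply(cohort, function(s) prepare_windows(s$recording, cfg))
  ids <- vapply(cohort, `[[`, character(1), "subject_id")
  ns <- vapply(sets, function(w) dim(w$windows)[1], integer(1))
  wsz <- sets[[1]]$window_sz
  arr <- array(0, dim = c(sum(ns), wsz, sets[[1]]$n_channels))
  at <- 0L
  for (i in seq_along(sets)) {
    if (ns[i] > 0) arr[at + seq_len(ns[i]), , ] <- sets[[i]]$windows
    at <- at + ns[i]
  }
  ws <- window_set(arr, unlist(lapply(sets, `[[`, "labels")),
                   unlist(lapply(sets, `[[`, "starts")),
                   wsz, sets[[1]]$sampling_rate_hz)
  attr(ws, "subjects") <- ids
  attr(ws, "window_subject") <- rep(ids, ns)
  ws
}

#' Subset a pooled window set to given subjects
#'
#' @param ws A [window_set()] from [cohort_windows()].
#' @param subjects Character vector of subject ids.
#' @return A [window_set()] restricted to those subjects.
#' @export
subset_windows <- function(ws, subjects) {
  wsub <- attr(ws, "window_subject")
  keep <- wsub %in% subjects
  out <- window_set(ws$windows[keep, , , drop = FALSE], ws$labels[keep],
                    ws$starts[keep], ws$window_sz, ws$sampling_rate_hz)
  attr(out, "subjects") <- subjects
  attr(out, "window_subject") <- wsub[keep]
  out
}

# Windows may live at the downsampled target rate; map their starts and
# length back to source-rate samples before building a per-sample mask.
rescale_predictions <- function(preds, source_rate_hz) {
  f <- source_rate_hz / preds$sampling_rate_hz
  if (f != 1) {
    preds$starts <- as.integer(round(preds$starts * f))
    preds$window_sz <- as.integer(round(preds$window_sz * f))
    preds$sampling_rate_hz <- source_rate_hz
  }
  preds
}

#' End-to-end detector comparison on a labeled recording
#'
#' Runs both detectors on the same recording and reports per-sample metrics
#' for each: the harmonic heuristic via [detect_gait()], and the classifier
#' via windowing, [predict.har_model()] and [predictions_to_mask()].
#'
#' @param lrec A harmonized, calibrated [labeled_recording()].
#' @param model A trained `har_model` (or `NULL` to skip the ML side).
#' @param cfg A `run_config`.
#' @param fcfg A [freq_detector_config()].
#' @return List with `freq` and `ml` `metrics_report`s (and the masks).
#' @export
compare_detectors <- function(lrec, model = NULL, cfg = default_config(),
                              fcfg = freq_detector_config()) {
  n <- n_samples(lrec)
  truth <- gait_mask(lrec$labels == "walking",
                     lrec$recording$meta$sampling_rate_hz, "truth")
  valid <- lrec$labels != "unlabeled"
  fmask <- detect_gait(lrec$recording, fcfg)
  out <- list(freq = mask_report(truth, fmask, valid, wilson = TRUE),
              freq_mask = fmask, truth = truth)
  if (!is.null(model)) {
    ws <- prepare_windows(lrec, cfg)
    preds <- predict(model, ws)
    preds <- rescale_predictions(preds, lrec$recording$meta$sampling_rate_hz)
    mmask <- predictions_to_mask(preds, n)
    out$ml <- mask_report(truth, mmask, valid, wilson = TRUE)
    out$ml_mask <- mmask
  }
  out
}

#' Write a synthetic recording and its ground truth to disk
#'
#' The recording goes to `<stem>.csv` in the generic IMU dialect; the
#' ground-truth walking mask and planted events to `<stem>_truth.csv` and
#' `<stem>_events.csv`.
#'
#' @param lrec A [labeled_recording()] from the generator.
#' @param stem Output path stem (no extension).
#' @return The recording CSV path, invisibly.
#' @export
write_synth_recording <- function(lrec, stem) {
  rec <- lrec$recording
  d <- data.frame(time_s = rec$time_s,
                  ax = rec$accel[, 1], ay = rec$accel[, 2], az = rec$accel[, 3],
                  gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3],
                  label = lrec$labels)
  write_csv_checked(d, paste0(stem, ".csv"))
  truth <- attr(lrec, "truth")
  if (!is.null(truth)) {
    write_csv_checked(
      data.frame(sample_index = seq_along(truth) - 1L,
                 is_walking = as.integer(truth)),
      paste0(stem, "_truth.csv"))
  }
  ev <- attr(lrec, "events")
  if (!is.null(ev) && length(ev$midswing) + length(ev$heelstrike) > 0) {
    write_csv_checked(
      data.frame(kind = c(rep("midswing", length(ev$midswing)),
                          rep("heelstrike", length(ev$heelstrike))),
                 sample_index = c(ev$midswing, ev$heelstrike) - 1L),
      paste0(stem, "_events.csv"))
  }
  invisible(paste0(stem, ".csv"))
}
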