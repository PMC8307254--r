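#' Zero-phase notch filter for power-line noise
#'
#' Removes mains interference with a narrow Butterworth band-reject
#' (quality ~30, i.e. 2 Hz stop bandwidth at 60 Hz) applied
#' forward-backward (`filtfilt`), so the output has no group delay.
#'
#' @param recording An [eeg_recording()].
#' @param line_freq Line frequency in Hz (default 60); must be below
#'   Nyquist.
#' @return The recording with every channel notch-filtered.
#' @export
notch_filter <- function(recording, line_freq = 60) {
  fs <- recording$sampling_rate
  if (line_freq >= fs / 2) stop("line_freq must be below Nyquist (fs/2)")
  bw <- line_freq / 30  # quality factor 30
  flt <- signal::butter(2, c(line_freq - bw / 2, line_freq + bw / 2) / (fs / 2),
                        type = "stop")
  apply_filter(recording, function(x) signal::filtfilt(flt, x))
}

#' Zero-phase band-pass filter
#'
#' Restricts every channel to the analysis band (default 0.5-44 Hz) with a
#' cascade of Butterworth high-pass (order 4) and low-pass (order 6)
#' stages, each applied forward-backward for zero phase. The cascade gives
#' >= 20 dB attenuation at `low / 2` and at `high + 10` Hz while keeping
#' the pass-band flat within 1 dB.
#'
#' @param recording An [eeg_recording()].
#' @param low,high Corner frequencies in Hz, `0 < low < high < fs/2`.
#' @return The filtered recording.
#' @export
bandpass_filter <- function(recording, low = 0.5, high = 44) {
  fs <- recording$sampling_rate
  if (!(low > 0 && low < high && high < fs / 2)) {
    stop("need 0 < low < high < fs/2")
  }
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(6, high / (fs / 2), type = "low")
  apply_filter(recording, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  })
}

apply_filter <- function(recording, f) {
  out <- recording
  for (i in seq_len(nrow(out$samples))) {
    out$samples[i, ] <- f(out$samples[i, ])
  }
  out
}

#' Reference-channel artifact regression
#'
#' Removes eye-blink and muscle contamination by replacing each scalp
#' channel with its residual after least-squares regression on the VEOG and
#' EMG reference channels (with intercept), fitted separately within each
#' contiguous annotation interval. This deterministic stand-in for
#' component-based denoising removes exactly the reference-correlated part
#' of every channel. The reference channels are dropped from the output's
#' channel set and kept under `$references`.
#'
#' @param recording An [eeg_recording()] containing `VEOG` and `EMG`
#'   channels. Samples outside annotated intervals pass through unchanged.
#' @return The recording restricted to scalp channels, artifact-regressed.
#' @export
remove_artifacts <- function(recording) {
  mont <- montage_channels()
  for (ref in mont$reference) {
    if (!ref %in% recording$channel_labels) {
      stop("missing reference channel: ", ref)
    }
  }
  fs <- recording$sampling_rate
  scalp <- intersect(recording$channel_labels, mont$scalp)
  refs <- recording$samples[mont$reference, , drop = FALSE]
  cleaned <- recording$samples[scalp, , drop = FALSE]
  ann <- recording$annotations
  intervals <- if (nrow(ann) > 0L) {
    lapply(seq_len(nrow(ann)), function(i) {
      (round(ann$start[i] * fs) + 1):round(ann$end[i] * fs)
    })
  } else {
    list(seq_len(ncol(cleaned)))
  }
  for (idx in intervals) {
    X <- cbind(1, t(refs[, idx, drop = FALSE]))
    for (ch in seq_len(nrow(cleaned))) {
      fit <- stats::lm.fit(X, cleaned[ch, idx])
      cleaned[ch, idx] <- fit$residuals
    }
  }
  out <- eeg_recording(cleaned, fs, scalp, ann, recording$group,
                       recording$subject_id)
  out$references <- refs
  out
}

#' Cut a recording into fixed-width task epochs
#'
#' Slices non-overlapping consecutive epochs of `epoch_len` seconds within
#' each annotated task interval; trailing partial windows are discarded and
#' intervals shorter than one epoch contribute none. Only scalp channels
#' are retained.
#'
#' @param recording An annotated [eeg_recording()].
#' @param epoch_len Epoch length in seconds (default 10).
#' @return List of [eeg_epoch()] objects, each carrying its task label and
#'   workload level.
#' @export
epoch_recording <- function(recording, epoch_len = 10) {
  ann <- recording$annotations
  if (nrow(ann) == 0L) stop("recording has no annotations to epoch")
  fs <- recording$sampling_rate
  scalp <- intersect(recording$channel_labels, montage_channels()$scalp)
  samples <- recording$samples[scalp, , drop = FALSE]
  n_ep <- round(epoch_len * fs)
  epochs <- list()
  for (i in seq_len(nrow(ann))) {
    i0 <- round(ann$start[i] * fs)
    n_int <- round((ann$end[i] - ann$start[i]) * fs)
    k <- n_int %/% n_ep
    for (j in seq_len(k)) {
      idx <- (i0 + (j - 1) * n_ep + 1):(i0 + j * n_ep)
      epochs[[length(epochs) + 1L]] <-
        eeg_epoch(samples[, idx, drop = FALSE], fs, scalp, ann$task[i],
                  recording$subject_id, recording$group)
    }
  }
  epochs
}

#' Optional peak-to-peak epoch rejection
#'
#' Drops epochs whose peak-to-peak amplitude on any channel exceeds a
#' threshold. Off by default in the pipeline (no rejection threshold is
#' part of the standard analysis); provided as a configurable guard for
#' noisy real recordings.
#'
#' @param epochs List of [eeg_epoch()].
#' @param threshold Peak-to-peak limit in microvolts.
#' @return The retained epochs.
#' @export
reject_epochs <- function(epochs, threshold = Inf) {
  if (!is.finite(threshold)) return(epochs)
  keep <- vapply(epochs, function(e) {
    all(apply(e$samples, 1, function(x) diff(range(x))) <= threshold)
  }, logical(1))
  epochs[keep]
}
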