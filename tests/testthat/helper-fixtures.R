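# Shared fixtures: all built in code, scaled small for speed.

# A single-channel epoch holding an arbitrary signal.
signal_epoch <- function(x, fs, task = "resting", channel = "Fz") {
  eeg_epoch(matrix(x, nrow = 1), fs, channel, task)
}

sine_epoch <- function(freq, fs = 200, duration = 10, amplitude = 1,
                       channel = "Fz") {
  t <- (seq_len(duration * fs) - 1) / fs
  signal_epoch(amplitude * sin(2 * pi * freq * t), fs, channel = channel)
}

# Synthetic PSD object with explicit per-channel spectra on a 0.5 Hz grid
# covering 0-f_max Hz.
flat_psd <- function(levels, f_max = 100, df = 0.5,
                     channels = names(levels),
                     shape = NULL) {
  freqs <- seq(0, f_max, by = df)
  if (is.null(channels)) channels <- paste0("ch", seq_along(levels))
  psd <- matrix(0, nrow = length(levels), ncol = length(freqs),
                dimnames = list(channels, NULL))
  for (i in seq_along(levels)) {
    psd[i, ] <- if (is.null(shape)) levels[[i]] else levels[[i]] * shape(freqs)
  }
  structure(list(freqs = freqs, psd = psd, df = df,
                 channel_labels = channels,
                 task_label = "resting", workload_level = 0L,
                 subject_id = "synthetic", group = NA_character_),
            class = "eeg_psd")
}

# PSD that is `level` on [low, high) Hz and zero elsewhere, per channel.
banded_psd <- function(low, high, level = 1, channels = "Fz", f_max = 100) {
  sp <- flat_psd(stats::setNames(as.list(rep(0, length(channels))), channels),
                 f_max = f_max)
  for (i in seq_along(channels)) {
    sp$psd[i, sp$freqs >= low & sp$freqs < high] <- level
  }
  sp
}

# Small fast cohort spec used across unit tests.
tiny_cohort_spec <- function(..., seed = 421) {
  cohort_spec(
    n_stroke = 2, n_control = 2,
    sampling_rate = 250,
    task_sequence = default_task_sequence(30),
    blink_rate = 0, emg_burst_rate = 0,
    seed = seed,
    ...
  )
}

# Gaussian feature table for classifier tests: `shift` is the per-feature
# group mean separation in SDs.
gaussian_feature_table <- function(n_subj_per_group = 6, epochs_per_subj = 8,
                                   n_features = 5, shift = 0, seed = 99) {
  set.seed(seed)
  rows <- list()
  for (g in c("stroke", "control")) {
    for (s in seq_len(n_subj_per_group)) {
      sid <- sprintf("%s_%02d", g, s)
      mu <- if (g == "stroke") shift else 0
      for (e in seq_len(epochs_per_subj)) {
        feats <- stats::rnorm(n_features, mean = mu)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, task = "resting",
          workload_level = 0L, epoch_index = e,
          t(stats::setNames(feats, sprintf("f%02d__feat__all", seq_len(n_features)))),
          stringsAsFactors = FALSE, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("feature_table", "data.frame")
  out
}
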