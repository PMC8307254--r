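#' Welch power spectral density of one epoch
#'
#' Estimates the per-channel PSD of a 10-s epoch by Welch's method:
#' Hamming-windowed segments (default 2 s, giving a 0.5 Hz grid that aligns
#' bins exactly with the canonical band edges), 50% overlap, one-sided
#' density scaling in uV^2/Hz. The estimate is Parseval-consistent: the
#' integral of the PSD over \[0, Nyquist\] matches the windowed signal
#' variance.
#'
#' @param epoch An [eeg_epoch()] (or any object with `$samples`,
#'   `$sampling_rate`, `$channel_labels`).
#' @param segment_len Segment length in seconds (default 2).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return Object of class `eeg_psd`: `freqs` (Hz), `psd` (channels x
#'   freqs, uV^2/Hz), and epoch metadata.
#' @export
welch_psd <- function(epoch, segment_len = 2, overlap = 0.5) {
  fs <- epoch$sampling_rate
  nper <- round(segment_len * fs)
  n <- ncol(epoch$samples)
  if (n < nper) stop("epoch shorter than one Welch segment")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- hamming_window(nper)
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1
  freqs <- (0:(nfreq - 1)) * fs / nper

  psd <- matrix(0, nrow = nrow(epoch$samples), ncol = nfreq,
                dimnames = list(epoch$channel_labels, NULL))
  for (ch in seq_len(nrow(psd))) {
    acc <- numeric(nfreq)
    for (s in starts) {
      seg <- epoch$samples[ch, s:(s + nper - 1)] * w
      P <- Mod(stats::fft(seg))^2 * scale
      half <- P[1:nfreq]
      # one-sided: double all bins except DC and Nyquist
      half[2:(nfreq - 1)] <- 2 * half[2:(nfreq - 1)]
      acc <- acc + half
    }
    psd[ch, ] <- acc / length(starts)
  }
  structure(
    list(
      freqs = freqs, psd = psd, df = fs / nper,
      channel_labels = epoch$channel_labels,
      task_label = epoch$task_label %||% NA_character_,
      workload_level = epoch$workload_level %||% NA_integer_,
      subject_id = epoch$subject_id %||% NA_character_,
      group = epoch$group %||% NA_character_
    ),
    class = "eeg_psd"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' @export
print.eeg_psd <- function(x, ...) {
  cat(sprintf("Welch PSD: %d channel(s), %.1f-%.1f Hz at df %.2f Hz\n",
              nrow(x$psd), min(x$freqs), max(x$freqs), x$df))
  invisible(x)
}

# Indices of the PSD bins belonging to a band (half-open [low, high),
# closed at the top for the final band).
band_bins <- function(spectrum, band) {
  if (is.character(band)) band <- band_definition(band)
  f <- spectrum$freqs
  if (band$low < min(f) - 1e-9 || band$high > max(f) + 1e-9) {
    stop("band [", band$low, ", ", band$high, "] outside the PSD grid")
  }
  keep <- f >= band$low - 1e-9 & (f < band$high - 1e-9)
  if (isTRUE(band$closed_top)) {
    keep <- keep | abs(f - band$high) < 1e-9
  }
  which(keep)
}

#' Absolute band power from a PSD
#'
#' Rectangle-rule integral of the PSD over the band's bins (half-open
#' `[low, high)` on the frequency grid; the gamma band closes at 44 Hz).
#'
#' @param spectrum An `eeg_psd`.
#' @param band Band name or one-row band definition.
#' @return Named numeric vector of band power (uV^2) per channel.
#' @export
band_power <- function(spectrum, band) {
  bins <- band_bins(spectrum, band)
  if (length(bins) == 0L) stop("band contains no frequency bins")
  rowSums(spectrum$psd[, bins, drop = FALSE]) * spectrum$df
}

#' Absolute and relative band powers plus spectral summaries
#'
#' Computes per-channel absolute power in the five canonical bands, the
#' relative powers against the four-band denominator
#' delta + theta + alpha + beta (gamma is excluded from the denominator but
#' its relative power is reported against the same denominator, so the four
#' denominator bands sum to exactly 1), total 0.5-44 Hz power, and the
#' spectral summary statistics of [spectral_summary()].
#'
#' @param spectrum An `eeg_psd`.
#' @return Object of class `band_power_vector`: matrices `abs_power` and
#'   `rel_power` (channels x bands), `total_power`, and the summary columns.
#'   Channels with an all-zero four-band denominator get `NA` relative
#'   powers (undefined-feature marker).
#' @export
relative_power <- function(spectrum) {
  bands <- eeg_bands()
  absp <- sapply(bands$name, function(b) band_power(spectrum, b))
  if (is.null(dim(absp))) absp <- matrix(absp, nrow = 1,
                                         dimnames = list(spectrum$channel_labels,
                                                         bands$name))
  denom <- rowSums(absp[, rp_denominator_bands(), drop = FALSE])
  rel <- absp / denom
  rel[denom <= 0, ] <- NA_real_
  summ <- spectral_summary(spectrum)
  structure(
    list(
      abs_power = absp, rel_power = rel,
      total_power = rowSums(absp),
      mean_freq = summ$mean_freq, median_freq = summ$median_freq,
      peak_freq = summ$peak_freq, spectral_edge_95 = summ$spectral_edge_95,
      channel_labels = spectrum$channel_labels,
      task_label = spectrum$task_label, workload_level = spectrum$workload_level,
      subject_id = spectrum$subject_id, group = spectrum$group
    ),
    class = "band_power_vector"
  )
}

#' Spectral summary statistics
#'
#' Power-weighted mean frequency, median frequency (50% cumulative power),
#' peak frequency (argmax bin) and 95% spectral edge frequency, all
#' computed over the 0.5-44 Hz analysis range. Channels with zero total
#' power get `NA` markers.
#'
#' @param spectrum An `eeg_psd`.
#' @param edge Cumulative-power fraction of the spectral edge (default
#'   0.95).
#' @return List of per-channel named vectors `mean_freq`, `median_freq`,
#'   `peak_freq`, `spectral_edge_95` (Hz).
#' @export
spectral_summary <- function(spectrum, edge = 0.95) {
  f <- spectrum$freqs
  keep <- f >= 0.5 - 1e-9 & f <= 44 + 1e-9
  fr <- f[keep]
  nch <- nrow(spectrum$psd)
  out <- list(mean_freq = numeric(nch), median_freq = numeric(nch),
              peak_freq = numeric(nch), spectral_edge_95 = numeric(nch))
  for (ch in seq_len(nch)) {
    p <- spectrum$psd[ch, keep]
    tot <- sum(p)
    if (tot <= 0) {
      for (nm in names(out)) out[[nm]][ch] <- NA_real_
      next
    }
    cum <- cumsum(p) / tot
    out$mean_freq[ch] <- sum(fr * p) / tot
    out$median_freq[ch] <- fr[which(cum >= 0.5)[1]]
    out$peak_freq[ch] <- fr[which.max(p)]
    out$spectral_edge_95[ch] <- fr[which(cum >= edge)[1]]
  }
  for (nm in names(out)) names(out[[nm]]) <- spectrum$channel_labels
  out
}

#' Resting-state baseline of relative band power
#'
#' Arithmetic mean of the relative powers over a subject's resting epochs,
#' per channel and band; the reference against which task-induced
#' percent changes are expressed.
#'
#' @param epoch_features List of `band_power_vector` objects for one
#'   subject (any tasks; only resting epochs enter the mean).
#' @return Object of class `baseline_summary`: matrix `rel_power`
#'   (channels x bands) and `n_resting_epochs`.
#' @export
resting_baseline <- function(epoch_features) {
  rest <- Filter(function(f) identical(f$task_label, "resting"), epoch_features)
  if (length(rest) == 0L) stop("no resting epochs: baseline undefined")
  mats <- lapply(rest, function(f) f$rel_power)
  avg <- Reduce(`+`, mats) / length(mats)
  structure(
    list(rel_power = avg, n_resting_epochs = length(rest),
         subject_id = rest[[1]]$subject_id),
    class = "baseline_summary"
  )
}

#' Task-induced percent change relative to the resting baseline
#'
#' `100 * (p - baseline) / baseline`, the percentage change of a relative
#' power (or any feature) against the subject's resting mean; sign
#' preserved, so a value of -5 means a 5% decrease from rest.
#'
#' @param p Relative power value(s).
#' @param baseline Resting baseline value(s) (same shape); entries `<= 0`
#'   yield `NA` (undefined-feature marker).
#' @return Percent change, same shape as `p`.
#' @export
percent_change <- function(p, baseline) {
  out <- (p - baseline) / baseline * 100
  out[!is.finite(out) | baseline <= 0] <- NA_real_
  out
}
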