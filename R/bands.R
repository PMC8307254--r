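#' Canonical EEG frequency bands
#'
#' Returns the five canonical qEEG band definitions used throughout the
#' package: delta \[0.5, 4), theta \[4, 8), alpha \[8, 13), beta \[13, 30) and
#' gamma \[30, 44\] Hz. Bands are half-open on the right so that adjacent
#' bands never double-count a frequency bin; the top band (gamma) closes at
#' 44 Hz, the upper edge of the analysis band-pass.
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz) and
#'   `closed_top` (logical; `TRUE` only for the top band).
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low = c(0.5, 4, 8, 13, 30),
    high = c(4, 8, 13, 30, 44),
    closed_top = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Bands entering the relative-power denominator (gamma is excluded; gamma
# relative power is still reported against the same four-band denominator).
rp_denominator_bands <- function() c("delta", "theta", "alpha", "beta")

#' Look up one band definition by name
#'
#' @param name One of `"delta"`, `"theta"`, `"alpha"`, `"beta"`, `"gamma"`.
#' @return A one-row data.frame as in [eeg_bands()].
#' @export
band_definition <- function(name) {
  bands <- eeg_bands()
  i <- match(name, bands$name)
  if (is.na(i)) {
    stop("unknown band '", name, "'; expected one of ",
         paste(bands$name, collapse = ", "))
  }
  bands[i, , drop = FALSE]
}

#' Task labels and mental-workload levels
#'
#' The four analyzed task states and their ordinal workload scores:
#' resting = 0, walking = 1, working = 2, reading = 3.
#'
#' @return Named integer vector mapping task label to workload level.
#' @export
workload_levels <- function() {
  c(resting = 0L, walking = 1L, working = 2L, reading = 3L)
}

task_labels <- function() names(workload_levels())

#' Scalp and reference channel labels
#'
#' The six scalp positions of the recording montage (10-20 system) plus the
#' two artifact reference channels.
#'
#' @return List with elements `scalp` and `reference`.
#' @export
montage_channels <- function() {
  list(
    scalp = c("Fz", "C1", "C2", "T7", "T8", "Oz"),
    reference = c("VEOG", "EMG")
  )
}

#' Default homologous channel pairing
#'
#' Left/right homologous channel pairs used by the pairwise-derived brain
#' symmetry index and band-power asymmetry; by default the central pair
#' (C1, C2) and the temporal pair (T7, T8).
#'
#' @param pairs List of length-2 character vectors `c(left, right)`.
#' @return An object of class `channel_pairing`.
#' @export
channel_pairing <- function(pairs = list(c("C1", "C2"), c("T7", "T8"))) {
  if (length(pairs) < 1L) stop("at least one homologous pair is required")
  for (p in pairs) {
    if (length(p) != 2L || anyDuplicated(p)) {
      stop("each pair must be two distinct channel labels")
    }
  }
  structure(list(pairs = pairs), class = "channel_pairing")
}

#' @export
print.channel_pairing <- function(x, ...) {
  cat("Homologous channel pairing (left : right)\n")
  for (p in x$pairs) cat("  ", p[1], ":", p[2], "\n")
  invisible(x)
}
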