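#' Construct a multichannel EEG recording
#'
#' The container every pipeline stage consumes: a channels-by-time sample
#' matrix in microvolts, its sampling rate, per-channel labels, task-interval
#' annotations and subject metadata.
#'
#' @param samples Numeric matrix, channels x time, in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Character vector, one unique label per row of
#'   `samples`.
#' @param annotations Data.frame with columns `start`, `end` (seconds from
#'   recording start, half-open `[start, end)`) and `task` (one of resting,
#'   walking, working, reading). May have zero rows.
#' @param group `"stroke"` or `"control"` (or `NA` for unlabeled data).
#' @param subject_id Subject identifier string.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, sampling_rate, channel_labels,
                          annotations = empty_annotations(),
                          group = NA_character_, subject_id = "subject") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop("samples must be a numeric matrix")
  if (length(channel_labels) != nrow(samples)) {
    stop("channel_labels must match the number of sample rows")
  }
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  annotations <- validate_annotations(annotations,
                                      ncol(samples) / sampling_rate)
  if (!is.na(group) && !group %in% c("stroke", "control")) {
    stop("group must be 'stroke', 'control' or NA")
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      channel_labels = as.character(channel_labels),
      annotations = annotations,
      group = group,
      subject_id = subject_id
    ),
    class = "eeg_recording"
  )
}

empty_annotations <- function() {
  data.frame(start = numeric(0), end = numeric(0), task = character(0),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, duration) {
  ann <- as.data.frame(ann)
  required <- c("start", "end", "task")
  if (!all(required %in% names(ann))) {
    stop("annotations need columns start, end, task")
  }
  ann <- ann[required]
  if (nrow(ann) == 0L) return(ann)
  if (any(ann$end <= ann$start)) stop("annotation intervals must have end > start")
  if (any(ann$start < 0) || any(ann$end > duration + 1e-9)) {
    stop("annotations must lie within the recording duration")
  }
  bad <- setdiff(unique(ann$task), task_labels())
  if (length(bad)) {
    stop("unknown task label(s): ", paste(bad, collapse = ", "))
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  if (nrow(ann) > 1L && any(ann$start[-1] < ann$end[-nrow(ann)] - 1e-9)) {
    stop("annotations must be non-overlapping")
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("EEG recording:", x$subject_id,
      if (!is.na(x$group)) paste0("(", x$group, ")") else "", "\n")
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  cat(sprintf("  %.1f s at %g Hz; %d annotated interval(s)\n",
              ncol(x$samples) / x$sampling_rate, x$sampling_rate,
              nrow(x$annotations)))
  invisible(x)
}

recording_duration <- function(recording) {
  ncol(recording$samples) / recording$sampling_rate
}

channel_index <- function(recording, label) {
  i <- match(label, recording$channel_labels)
  if (is.na(i)) stop("channel '", label, "' not present in recording")
  i
}

#' Construct a fixed-length EEG epoch
#'
#' @param samples Numeric matrix, scalp channels x time (microvolts).
#' @param sampling_rate Hz.
#' @param channel_labels Channel labels for the rows.
#' @param task_label Task state of the epoch.
#' @param subject_id,group Subject metadata carried through the pipeline.
#' @return An object of class `eeg_epoch`; `workload_level` is derived from
#'   the task label (resting 0, walking 1, working 2, reading 3).
#' @export
eeg_epoch <- function(samples, sampling_rate, channel_labels, task_label,
                      subject_id = "subject", group = NA_character_) {
  samples <- as.matrix(samples)
  lv <- workload_levels()
  if (!task_label %in% names(lv)) stop("unknown task label: ", task_label)
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      channel_labels = as.character(channel_labels),
      task_label = task_label,
      workload_level = unname(lv[task_label]),
      subject_id = subject_id,
      group = group
    ),
    class = "eeg_epoch"
  )
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("EEG epoch: %s/%s, %.1f s at %g Hz, workload %d\n",
              x$subject_id, x$task_label, ncol(x$samples) / x$sampling_rate,
              x$sampling_rate, x$workload_level))
  invisible(x)
}
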