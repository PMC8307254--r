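# 10-20 label aliases accepted by the readers (case-insensitive matching is
# applied on top of these).
channel_aliases <- function() {
  c(FZ = "Fz", OZ = "Oz", C1 = "C1", C2 = "C2", T7 = "T7", T8 = "T8",
    T3 = "T7", T4 = "T8", VEOG = "VEOG", EOG = "VEOG", EMG = "EMG",
    CHIN_EMG = "EMG")
}

normalize_labels <- function(labels) {
  al <- channel_aliases()
  up <- toupper(labels)
  out <- labels
  hit <- up %in% names(al)
  out[hit] <- unname(al[up[hit]])
  out
}

#' Read a recording from disk
#'
#' Reads EDF (via the built-in 16-bit reader) or wide CSV (one column per
#' channel, header row of labels). Channel labels are matched
#' case-insensitively with common 10-20 aliases (T3/T4 map to T7/T8, EOG to
#' VEOG). Annotations come from the EDF sidecar or an explicit CSV with
#' columns start,end,task. A missing scalp channel is an error naming the
#' channel; missing reference channels are tolerated here and only fail
#' later in [remove_artifacts()].
#'
#' @param path Input file.
#' @param format `"edf"` or `"csv"` (default guessed from the extension).
#' @param sampling_rate Required for CSV input (Hz).
#' @param annotations Optional annotations CSV path.
#' @param group,subject_id Optional metadata.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           sampling_rate = NULL, annotations = NULL,
                           group = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  rec <- if (format == "edf") {
    read_edf(path, annotations = annotations, group = group,
             subject_id = subject_id)
  } else {
    if (is.null(sampling_rate)) stop("sampling_rate is required for CSV input")
    df <- utils::read.csv(path, check.names = FALSE)
    labels <- normalize_labels(names(df))
    ann <- if (!is.null(annotations)) {
      utils::read.csv(annotations, stringsAsFactors = FALSE)
    } else {
      empty_annotations()
    }
    eeg_recording(t(as.matrix(df)), sampling_rate, labels, ann,
                  group = group %||% NA_character_,
                  subject_id = subject_id %||%
                    sub("\\.[^.]*$", "", basename(path)))
  }
  rec$channel_labels <- normalize_labels(rec$channel_labels)
  rownames(rec$samples) <- rec$channel_labels
  missing <- setdiff(montage_channels()$scalp, rec$channel_labels)
  if (length(missing)) {
    stop("missing scalp channel(s): ", paste(missing, collapse = ", "))
  }
  rec
}

#' Write a synthetic cohort to disk
#'
#' Writes one EDF file (plus annotation sidecar) per subject and a cohort
#' manifest CSV (`subject_id`, `group`, `file`, `seed`).
#'
#' @param cohort List of [eeg_recording()] from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param spec The [cohort_spec()] used (for the manifest seed column).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    files[i] <- file.path(dir, paste0(cohort[[i]]$subject_id, ".edf"))
    write_edf(cohort[[i]], files[i])
  }
  manifest <- data.frame(
    subject_id = vapply(cohort, function(r) r$subject_id, ""),
    group = vapply(cohort, function(r) r$group, ""),
    file = basename(files),
    seed = if (is.null(spec)) NA_integer_ else spec$seed,
    stringsAsFactors = FALSE
  )
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the per-subject EDFs.
#' @return List of [eeg_recording()].
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_recording(file.path(dir, manifest$file[i]), format = "edf",
                   group = manifest$group[i],
                   subject_id = manifest$subject_id[i])
  })
}

#' Write a feature table in long format
#'
#' Long-format export (subject_id, group, task, workload_level, channel,
#' feature_name, band, value), the interchange format of the feature stage.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features_long <- function(table, path) {
  meta <- meta_columns(table)
  feats <- setdiff(names(table), meta)
  parts <- strsplit(feats, "__", fixed = TRUE)
  long <- do.call(rbind, lapply(seq_along(feats), function(j) {
    p <- parts[[j]]
    data.frame(
      table[meta],
      channel = p[1], feature_name = p[2], band = p[3],
      value = table[[feats[j]]],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
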