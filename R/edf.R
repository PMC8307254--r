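# Minimal EDF (European Data Format, 16-bit) writer/reader in base R.
# One data record per second; physical range chosen per channel from the
# data; start date/time fixed so identical input yields identical bytes.

pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

# format a number so it fits an 8-character EDF header field
fmt8 <- function(x) {
  vapply(x, function(v) {
    for (d in 7:1) {
      s <- formatC(v, format = "g", digits = d)
      if (nchar(s) <= 8) return(s)
    }
    stop("value does not fit an EDF header field: ", v)
  }, "")
}

#' Write a recording to an EDF file
#'
#' Serializes an [eeg_recording()] to 16-bit EDF. Each channel is scaled to
#' its own physical min/max, so round-tripping is exact up to the 16-bit
#' quantization step. Annotations are written to a sidecar CSV
#' (`<path>.annotations.csv`, columns start,end,task) rather than an EDF+
#' annotation channel.
#'
#' @param recording An [eeg_recording()].
#' @param path Output file path (conventionally `.edf`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  ns <- nrow(recording$samples)
  n <- ncol(recording$samples)
  n_rec <- ceiling(n / fs)
  # pad the final partial second with zeros
  x <- matrix(0, nrow = ns, ncol = n_rec * fs)
  x[, seq_len(n)] <- recording$samples

  pmin_ <- apply(x, 1, min)
  pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8),
    pad(recording$subject_id, 80),
    pad(paste("group", recording$group), 80),
    pad("01.01.00", 8), pad("00.00.00", 8),
    pad(256 * (1 + ns), 8),
    pad("", 44),
    pad(n_rec, 8),
    pad("1", 8),
    pad(ns, 4)
  )
  fld <- function(vals, width) paste0(vapply(vals, pad, "", width = width),
                                      collapse = "")
  hdr <- paste0(
    hdr,
    fld(recording$channel_labels, 16),
    fld(rep("", ns), 80),                      # transducer
    fld(rep("uV", ns), 8),                     # physical dimension
    fld(fmt8(pmin_), 8),
    fld(fmt8(pmax_), 8),
    fld(rep(dmin, ns), 8),
    fld(rep(dmax, ns), 8),
    fld(rep("", ns), 80),                      # prefiltering
    fld(rep(fs, ns), 8),
    fld(rep("", ns), 32)
  )
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)
  # re-read the printed physical limits so scaling matches what a reader sees
  pmin_r <- as.numeric(fmt8(pmin_))
  pmax_r <- as.numeric(fmt8(pmax_))
  scale <- (pmax_r - pmin_r) / (dmax - dmin)
  dig <- matrix(0L, nrow = ns, ncol = ncol(x))
  for (ch in seq_len(ns)) {
    d <- round((x[ch, ] - pmin_r[ch]) / scale[ch]) + dmin
    dig[ch, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    # record layout: all samples of signal 1, then signal 2, ...
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con,
             size = 2, endian = "little")
  }
  ann_path <- paste0(path, ".annotations.csv")
  utils::write.csv(recording$annotations, ann_path, row.names = FALSE)
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal 16-bit EDF reader matching [write_edf()]. Annotations are taken
#' from a sidecar CSV (`<path>.annotations.csv` by default).
#'
#' @param path EDF file path.
#' @param annotations Optional path to a sidecar annotations CSV (columns
#'   start,end,task); defaults to `<path>.annotations.csv` when that file
#'   exists.
#' @param group,subject_id Optional metadata overrides; defaults parsed
#'   from the EDF header.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, annotations = NULL, group = NULL,
                     subject_id = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) {
    trimws(readChar(con, width, useBytes = TRUE))
  }
  rd(8)                                   # version
  patient <- rd(80)
  rec_field <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  rdv(80)
  rdv(8)
  pmin_ <- as.numeric(rdv(8))
  pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1L) stop("channels with mixed sampling rates are not supported")
  fs <- spr[1] / rec_dur
  x <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, integer(), n = ns * spr[1], size = 2,
                     endian = "little")
    for (ch in seq_len(ns)) {
      seg <- block[((ch - 1) * spr[1] + 1):(ch * spr[1])]
      x[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        pmin_[ch] + (seg - dmin[ch]) * (pmax_[ch] - pmin_[ch]) / (dmax[ch] - dmin[ch])
    }
  }
  ann <- empty_annotations()
  if (is.null(annotations)) {
    cand <- paste0(path, ".annotations.csv")
    if (file.exists(cand)) annotations <- cand
  }
  if (!is.null(annotations)) {
    ann <- utils::read.csv(annotations, stringsAsFactors = FALSE)
  }
  if (is.null(group)) {
    group <- sub("^group ", "", rec_field)
    if (!group %in% c("stroke", "control")) group <- NA_character_
  }
  eeg_recording(x, fs, labels, ann,
                group = group,
                subject_id = if (is.null(subject_id)) patient else subject_id)
}
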