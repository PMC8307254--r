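#' Delta-alpha ratio (DAR)
#'
#' Ratio of delta to alpha band power per channel; elevated slow-wave
#' activity after ischemic stroke raises it. Computed from relative powers,
#' which equals the absolute-power ratio since the denominators cancel.
#'
#' @param features A `band_power_vector` (see [relative_power()]).
#' @return Named per-channel vector; `NA` where alpha power is zero.
#' @export
dar <- function(features) {
  ratio_feature(features, "delta", "alpha")
}

#' Delta-theta ratio (DTR)
#'
#' Ratio of delta to theta band power per channel.
#'
#' @inheritParams dar
#' @return Named per-channel vector; `NA` where theta power is zero.
#' @export
dtr <- function(features) {
  ratio_feature(features, "delta", "theta")
}

ratio_feature <- function(features, num, den) {
  p <- features$rel_power
  out <- p[, num] / p[, den]
  out[!is.finite(out)] <- NA_real_
  names(out) <- features$channel_labels
  out
}

#' (Delta+Theta)/(Alpha+Beta) ratio (DTABR)
#'
#' Slow-over-fast power ratio per channel, computed on absolute band powers.
#'
#' @inheritParams dar
#' @return Named per-channel vector; `NA` where alpha + beta power is zero.
#' @export
dtabr <- function(features) {
  P <- features$abs_power
  out <- (P[, "delta"] + P[, "theta"]) / (P[, "alpha"] + P[, "beta"])
  out[!is.finite(out)] <- NA_real_
  names(out) <- features$channel_labels
  out
}

#' Pairwise-derived brain symmetry index (pdBSI)
#'
#' Mean over homologous channel pairs and 0.5 Hz frequency bins of the
#' normalized absolute left/right PSD difference
#' `|R - L| / (R + L)`, restricted to the 0.5-30 Hz range (the four
#' slow-to-beta bands). Ranges from 0 (perfectly symmetric hemispheres) to
#' 1 (totally asymmetric). Per-band components restrict the bins to one
#' band; bins with zero bilateral power are excluded.
#'
#' @param spectrum An `eeg_psd` containing both channels of every pair.
#' @param pairing A [channel_pairing()].
#' @param bands Character vector of band names defining the bin range
#'   (default the four denominator bands, i.e. 0.5-30 Hz).
#' @return List: `overall` (scalar), `per_band` (named vector over
#'   `bands`), `per_pair` (overall value per pair) and `per_pair_band`
#'   (pairs x bands matrix). Undefined values (all bins excluded) are `NA`.
#' @export
pdbsi <- function(spectrum, pairing = channel_pairing(),
                  bands = rp_denominator_bands()) {
  stopifnot(inherits(pairing, "channel_pairing"))
  bin_sets <- lapply(bands, function(b) band_bins(spectrum, b))
  names(bin_sets) <- bands
  npair <- length(pairing$pairs)
  per_pair_band <- matrix(NA_real_, nrow = npair, ncol = length(bands),
                          dimnames = list(
                            vapply(pairing$pairs, paste0, "", collapse = ""),
                            bands))
  ratios_all <- vector("list", npair)
  for (i in seq_len(npair)) {
    p <- pairing$pairs[[i]]
    L <- spectrum$psd[match_channel(spectrum, p[1]), ]
    R <- spectrum$psd[match_channel(spectrum, p[2]), ]
    pair_ratios <- list()
    for (b in bands) {
      idx <- bin_sets[[b]]
      s <- R[idx] + L[idx]
      ok <- s > 0
      r <- abs(R[idx][ok] - L[idx][ok]) / s[ok]
      per_pair_band[i, b] <- if (length(r)) mean(r) else NA_real_
      pair_ratios[[b]] <- r
    }
    ratios_all[[i]] <- unlist(pair_ratios, use.names = FALSE)
  }
  per_pair <- vapply(ratios_all, function(r) {
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  names(per_pair) <- rownames(per_pair_band)
  all_r <- unlist(ratios_all, use.names = FALSE)
  per_band <- vapply(bands, function(b) {
    r <- unlist(lapply(seq_len(npair), function(i) {
      idx <- bin_sets[[b]]
      p <- pairing$pairs[[i]]
      L <- spectrum$psd[match_channel(spectrum, p[1]), idx]
      R <- spectrum$psd[match_channel(spectrum, p[2]), idx]
      s <- R + L
      abs(R[s > 0] - L[s > 0]) / s[s > 0]
    }), use.names = FALSE)
    if (length(r)) mean(r) else NA_real_
  }, numeric(1))
  list(
    overall = if (length(all_r)) mean(all_r) else NA_real_,
    per_band = per_band,
    per_pair = per_pair,
    per_pair_band = per_pair_band
  )
}

match_channel <- function(spectrum, label) {
  i <- match(label, spectrum$channel_labels)
  if (is.na(i)) stop("channel '", label, "' not present in spectrum")
  i
}

#' Signed hemispheric band-power asymmetry
#'
#' Mean over homologous pairs of `(R - L) / (R + L)` on band-integrated
#' power: positive when the right hemisphere carries more power in the
#' band, in \[-1, 1\]. Pairs with zero bilateral band power are excluded.
#'
#' @param spectrum An `eeg_psd`.
#' @param pairing A [channel_pairing()].
#' @param band Band name or definition.
#' @return List: `overall` (mean over pairs) and `per_pair` (named
#'   vector); `NA` markers where undefined.
#' @export
band_asymmetry <- function(spectrum, pairing = channel_pairing(), band) {
  P <- band_power(spectrum, band)
  vals <- vapply(pairing$pairs, function(p) {
    L <- P[p[1]]; R <- P[p[2]]
    s <- R + L
    if (!is.finite(s) || s <= 0) NA_real_ else unname((R - L) / s)
  }, numeric(1))
  names(vals) <- vapply(pairing$pairs, paste0, "", collapse = "")
  list(overall = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
       per_pair = vals)
}

# Compute the full wide feature row(s) for one epoch: channel-level powers,
# summaries and ratios, pair-level pdBSI and asymmetry. Returns a named
# numeric vector; names follow scope__feature__band.
epoch_feature_vector <- function(epoch, pairing = channel_pairing(),
                                 welch_segment = 2, welch_overlap = 0.5) {
  sp <- welch_psd(epoch, welch_segment, welch_overlap)
  fv <- relative_power(sp)
  bands <- eeg_bands()$name
  out <- c()
  for (ch in fv$channel_labels) {
    out <- c(out,
             stats::setNames(fv$abs_power[ch, bands],
                             paste(ch, "abspow", bands, sep = "__")),
             stats::setNames(fv$rel_power[ch, bands],
                             paste(ch, "relpow", bands, sep = "__")),
             stats::setNames(fv$total_power[ch], paste(ch, "power", "total", sep = "__")),
             stats::setNames(fv$mean_freq[ch], paste(ch, "meanfreq", "all", sep = "__")),
             stats::setNames(fv$median_freq[ch], paste(ch, "medianfreq", "all", sep = "__")),
             stats::setNames(fv$peak_freq[ch], paste(ch, "peakfreq", "all", sep = "__")),
             stats::setNames(fv$spectral_edge_95[ch], paste(ch, "sef95", "all", sep = "__")))
  }
  d <- dar(fv); t <- dtr(fv); dt <- dtabr(fv)
  out <- c(out,
           stats::setNames(d, paste(names(d), "dar", "all", sep = "__")),
           stats::setNames(t, paste(names(t), "dtr", "all", sep = "__")),
           stats::setNames(dt, paste(names(dt), "dtabr", "all", sep = "__")))
  bsi <- pdbsi(sp, pairing)
  out <- c(out, stats::setNames(bsi$overall, "pair__pdbsi__overall"),
           stats::setNames(bsi$per_band,
                           paste("pair", "pdbsi", names(bsi$per_band), sep = "__")))
  for (pp in rownames(bsi$per_pair_band)) {
    out <- c(out, stats::setNames(bsi$per_pair[pp],
                                  paste(pp, "pdbsi", "overall", sep = "__")),
             stats::setNames(bsi$per_pair_band[pp, ],
                             paste(pp, "pdbsi", colnames(bsi$per_pair_band),
                                   sep = "__")))
  }
  for (b in bands) {
    asym <- band_asymmetry(sp, pairing, b)
    out <- c(out, stats::setNames(asym$overall, paste("pair", "asym", b, sep = "__")),
             stats::setNames(asym$per_pair,
                             paste(names(asym$per_pair), "asym", b, sep = "__")))
  }
  out
}

#' Extract per-epoch features for a set of epochs
#'
#' Runs the Welch PSD and the full feature/biomarker panel on every epoch
#' and returns a wide data.frame, one row per epoch, with metadata columns
#' (`subject_id`, `group`, `task`, `workload_level`, `epoch_index`) and one
#' column per feature (named `scope__feature__band`, where scope is a
#' channel, a homologous pair, or `pair` for the pair-mean).
#'
#' @param epochs List of [eeg_epoch()].
#' @param pairing A [channel_pairing()].
#' @param welch_segment,welch_overlap Welch settings passed to
#'   [welch_psd()].
#' @return Data.frame of per-epoch features.
#' @export
extract_features <- function(epochs, pairing = channel_pairing(),
                             welch_segment = 2, welch_overlap = 0.5) {
  if (length(epochs) == 0L) stop("no epochs supplied")
  rows <- lapply(epochs, epoch_feature_vector, pairing = pairing,
                 welch_segment = welch_segment, welch_overlap = welch_overlap)
  nm <- names(rows[[1]])
  mat <- do.call(rbind, lapply(rows, function(r) r[nm]))
  meta <- data.frame(
    subject_id = vapply(epochs, function(e) e$subject_id, ""),
    group = vapply(epochs, function(e) e$group %||% NA_character_, ""),
    task = vapply(epochs, function(e) e$task_label, ""),
    workload_level = vapply(epochs, function(e) e$workload_level, 0L),
    stringsAsFactors = FALSE
  )
  idx <- stats::ave(seq_len(nrow(meta)),
                    meta$subject_id, meta$task, FUN = seq_along)
  meta$epoch_index <- as.integer(idx)
  cbind(meta, as.data.frame(mat, optional = TRUE))
}

# Add per-channel, per-band percent-change columns (relative power vs the
# subject's resting baseline) to a per-epoch feature table.
add_percent_change <- function(feature_df) {
  bands <- eeg_bands()$name
  scalp <- montage_channels()$scalp
  rel_cols <- as.vector(outer(scalp, bands,
                              function(ch, b) paste(ch, "relpow", b, sep = "__")))
  rel_cols <- rel_cols[rel_cols %in% names(feature_df)]
  for (col in rel_cols) {
    new <- sub("__relpow__", "__rpchange__", col)
    feature_df[[new]] <- NA_real_
  }
  for (sid in unique(feature_df$subject_id)) {
    rows <- feature_df$subject_id == sid
    rest <- rows & feature_df$task == "resting"
    if (!any(rest)) next
    for (col in rel_cols) {
      base <- mean(feature_df[rest, col], na.rm = TRUE)
      new <- sub("__relpow__", "__rpchange__", col)
      feature_df[rows, new] <- percent_change(feature_df[rows, col], base)
    }
  }
  feature_df
}

#' Assemble the subject x task feature table
#'
#' Builds the analysis-ready feature table from per-epoch features:
#' either one row per epoch (`"per-epoch"`, the classification default,
#' larger sample for the 70/30 split) or epoch means within each
#' (subject, task) cell (`"per-task-mean"`, the group-statistics default).
#' Percent-change columns relative to each subject's resting baseline are
#' appended before aggregation. Missing markers (`NA`) propagate through
#' the mean pairwise.
#'
#' @param feature_df Per-epoch feature data.frame from
#'   [extract_features()].
#' @param aggregation `"per-epoch"` or `"per-task-mean"`.
#' @return Object of class `feature_table` (a data.frame with the metadata
#'   columns first).
#' @export
build_feature_table <- function(feature_df,
                                aggregation = c("per-epoch", "per-task-mean")) {
  aggregation <- match.arg(aggregation)
  key <- paste(feature_df$subject_id, feature_df$task, feature_df$epoch_index)
  if (anyDuplicated(key)) stop("duplicate (subject, task, epoch) rows")
  grp <- tapply(feature_df$group, feature_df$subject_id,
                function(g) length(unique(g)))
  if (any(grp > 1)) stop("a subject appears with more than one group label")
  feature_df <- add_percent_change(feature_df)
  meta_cols <- c("subject_id", "group", "task", "workload_level", "epoch_index")
  feat_cols <- setdiff(names(feature_df), meta_cols)
  feat_cols <- sort(feat_cols)  # deterministic column ordering
  if (aggregation == "per-epoch") {
    out <- feature_df[c(meta_cols, feat_cols)]
  } else {
    sk <- interaction(feature_df$subject_id, feature_df$task, drop = TRUE)
    first <- !duplicated(sk)
    out <- feature_df[first, c("subject_id", "group", "task", "workload_level")]
    agg <- apply(feature_df[feat_cols], 2, function(v) {
      tapply(v, sk, function(x) {
        if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
      })
    })
    out <- cbind(out, as.data.frame(agg[as.character(sk[first]), , drop = FALSE],
                                    optional = TRUE))
  }
  out <- out[order(out$subject_id, out$workload_level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Names of the non-feature metadata columns of a feature table
#' @param table A `feature_table`.
#' @return Character vector of metadata column names present.
#' @export
meta_columns <- function(table) {
  intersect(c("subject_id", "group", "task", "workload_level", "epoch_index"),
            names(table))
}

#' @export
print.feature_table <- function(x, ...) {
  nf <- ncol(x) - length(meta_columns(x))
  cat(sprintf("qEEG feature table: %d rows x %d features (%s)\n",
              nrow(x), nf,
              if ("epoch_index" %in% names(x)) "per-epoch" else "per-task-mean"))
  cat("  subjects:", length(unique(x$subject_id)),
      " groups:", paste(names(table(x$group)), table(x$group),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}
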