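#' Levene-gated independent-samples t-test
#'
#' The two-stage comparison used per feature: Levene's test for equality of
#' variances (mean-centered, the classical form) at alpha = 0.05 decides
#' between the pooled-variance t-test and Welch's unequal-variance t-test;
#' the two-sided t p-value is reported.
#'
#' @param values_a,values_b Numeric samples (missing values dropped); each
#'   needs at least 2 non-missing values.
#' @param alpha Significance level for both the Levene gate and the
#'   significance flag (default 0.05).
#' @return One-row data.frame: group means/SDs, `levene_p`, `t_statistic`,
#'   `t_p`, `equal_variance_assumed`, `significant`. All-`NA` marker row if
#'   either sample is too small.
#' @export
levene_gated_ttest <- function(values_a, values_b, alpha = 0.05) {
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(data.frame(mean_a = NA_real_, sd_a = NA_real_, mean_b = NA_real_,
                      sd_b = NA_real_, levene_p = NA_real_,
                      t_statistic = NA_real_, t_p = NA_real_,
                      equal_variance_assumed = NA, significant = NA))
  }
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  # suppressWarnings: near-constant samples make the Levene F unreliable,
  # which the NA/gate handling below already degrades gracefully
  lev <- tryCatch(
    suppressWarnings(car::leveneTest(y, g, center = mean)[1, "Pr(>F)"]),
    error = function(e) NA_real_
  )
  equal_var <- is.na(lev) || lev >= alpha
  tt <- tryCatch(stats::t.test(a, b, var.equal = equal_var),
                 error = function(e) NULL)
  if (is.null(tt)) {
    # both samples constant and equal: no variance at all
    t_stat <- if (mean(a) == mean(b)) 0 else NA_real_
    t_p <- if (mean(a) == mean(b)) 1 else NA_real_
  } else {
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  data.frame(
    mean_a = mean(a), sd_a = stats::sd(a),
    mean_b = mean(b), sd_b = stats::sd(b),
    levene_p = lev, t_statistic = t_stat, t_p = t_p,
    equal_variance_assumed = equal_var,
    significant = !is.na(t_p) && t_p < alpha
  )
}

#' Screen out constant and mostly-missing feature columns
#'
#' Early screening before ranking: drops feature columns that are constant
#' (zero variance over non-missing values) or whose missing fraction
#' exceeds `max_missing`.
#'
#' @param table A `feature_table`.
#' @param max_missing Maximum tolerated missing fraction (default 0.2).
#' @return The screened `feature_table`; errors if nothing survives.
#' @export
screen_features <- function(table, max_missing = 0.2) {
  meta <- meta_columns(table)
  feats <- setdiff(names(table), meta)
  keep <- vapply(feats, function(col) {
    v <- table[[col]]
    miss <- mean(is.na(v))
    if (miss > max_missing) return(FALSE)
    v <- v[!is.na(v)]
    length(unique(v)) > 1L
  }, logical(1))
  if (!any(keep)) stop("screening dropped every feature column")
  out <- table[c(meta, feats[keep])]
  class(out) <- class(table)
  out
}

#' Chi-square feature importance
#'
#' Importance of one feature for the group label, defined as `1 - p` from
#' Pearson's chi-square test of independence between the discretized
#' feature and the label. Continuous features are discretized into
#' equal-frequency bins (default 10; ties can force fewer). Equal-frequency
#' binning makes the importance invariant to strictly monotone transforms
#' of the feature (up to ties).
#'
#' @param values Numeric feature values.
#' @param labels Group labels (>= 2 classes among non-missing rows).
#' @param bins Target number of equal-frequency bins.
#' @return Importance in \[0, 1\]; 0 (with a warning) if the feature
#'   degenerates to a single bin.
#' @export
chi_square_importance <- function(values, labels, bins = 10) {
  ok <- !is.na(values) & !is.na(labels)
  values <- values[ok]
  labels <- factor(labels[ok])
  if (nlevels(labels) < 2L) stop("need at least two label classes")
  qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, names = FALSE, type = 7))
  if (length(qs) < 3L) {
    warning("degenerate binning (single bin); importance set to 0")
    return(0)
  }
  binned <- cut(values, breaks = qs, include.lowest = TRUE)
  tab <- table(binned, labels)
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (nrow(tab) < 2L) {
    warning("degenerate binning (single bin); importance set to 0")
    return(0)
  }
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  if (is.na(p)) return(0)
  1 - p
}

#' Rank features by chi-square importance
#'
#' @param table A screened `feature_table` with a `group` column.
#' @param bins Bins for [chi_square_importance()].
#' @param by_task If `TRUE`, importance is computed within each task and
#'   the maximum over tasks is used for ranking; default pools all rows.
#' @return Data.frame (class `importance_ranking`): `feature`,
#'   `importance`, `rank` (descending importance, ties by feature name).
#' @export
rank_features <- function(table, bins = 10, by_task = FALSE) {
  feats <- setdiff(names(table), meta_columns(table))
  imp <- vapply(feats, function(col) {
    v <- table[[col]]
    if (by_task) {
      max(vapply(unique(table$task), function(tk) {
        sel <- table$task == tk
        tryCatch(
          suppressWarnings(chi_square_importance(v[sel], table$group[sel], bins)),
          error = function(e) 0)
      }, numeric(1)))
    } else {
      tryCatch(suppressWarnings(chi_square_importance(v, table$group, bins)),
               error = function(e) 0)
    }
  }, numeric(1))
  ord <- order(-imp, feats)
  out <- data.frame(feature = feats[ord], importance = unname(imp[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("importance_ranking", "data.frame")
  out
}

#' Select features above the importance threshold
#'
#' Retains exactly the feature columns whose chi-square importance exceeds
#' `threshold` (default 0.95, the standard selection criterion), ordered by
#' descending importance with ties broken by column name.
#'
#' @param table A screened `feature_table`.
#' @param threshold Importance cut (features kept iff importance >
#'   threshold).
#' @param ranking Optional precomputed [rank_features()] result.
#' @param ... Passed to [rank_features()].
#' @return List: `table` (the selected `feature_table`, possibly with zero
#'   feature columns, with a warning) and `ranking` (with a `selected`
#'   flag column).
#' @export
select_features <- function(table, threshold = 0.95, ranking = NULL, ...) {
  if (is.null(ranking)) ranking <- rank_features(table, ...)
  ranking$selected <- ranking$importance > threshold
  sel <- ranking$feature[ranking$selected]
  if (length(sel) == 0L) {
    warning("no feature exceeds the importance threshold ", threshold)
  }
  out <- table[c(meta_columns(table), sel)]
  class(out) <- class(table)
  list(table = out, ranking = ranking)
}

#' Group comparison of every feature
#'
#' Runs the Levene-gated t-test stroke-versus-control for each feature
#' column, per task (and optionally on the pooled rows), mirroring the
#' descriptive-statistics stage of the analysis.
#'
#' @param table A `feature_table` with a `group` column containing both
#'   classes.
#' @param tasks Tasks to compare within (default: each task present plus
#'   the pooled `"all"`).
#' @param alpha Significance level.
#' @return Data.frame, one row per (feature, task): group means/SDs,
#'   Levene p, t statistic and p, and the significance flag.
#' @export
compare_groups <- function(table, tasks = NULL, alpha = 0.05) {
  if (is.null(tasks)) tasks <- c(sort(unique(table$task)), "all")
  feats <- setdiff(names(table), meta_columns(table))
  res <- list()
  for (tk in tasks) {
    rows <- if (tk == "all") rep(TRUE, nrow(table)) else table$task == tk
    a <- table$group[rows] == "stroke"
    for (col in feats) {
      v <- table[[col]][rows]
      cmp <- levene_gated_ttest(v[a], v[!a], alpha)
      res[[length(res) + 1L]] <- cbind(
        data.frame(feature = col, task = tk, stringsAsFactors = FALSE), cmp)
    }
  }
  out <- do.call(rbind, res)
  names(out) <- sub("_a$", "_stroke", sub("_b$", "_control", names(out)))
  rownames(out) <- NULL
  out
}
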