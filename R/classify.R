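#' Train/test split specification
#'
#' @param train_fraction Fraction of data assigned to training (default
#'   0.70).
#' @param stratified Stratify by class label (default `TRUE`).
#' @param group_aware Keep all rows of a subject on the same side of the
#'   split (default `TRUE`), preventing leakage between a subject's epochs.
#' @param seed Integer seed controlling the split.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.70, stratified = TRUE,
                       group_aware = TRUE, seed = 1L) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie in (0, 1)")
  }
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 group_aware = group_aware, seed = as.integer(seed)),
            class = "split_spec")
}

# Allocate per-stratum training counts: overall target round(f * n),
# distributed by largest fractional remainder, ties by stratum name.
allocate_train <- function(sizes, fraction) {
  total <- round(fraction * sum(sizes))
  base <- floor(fraction * sizes)
  rem <- fraction * sizes - base
  extra <- total - sum(base)
  if (extra > 0) {
    ord <- order(-rem, names(sizes))
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1L
  }
  pmin(pmax(base, 1L), sizes - 1L)  # keep both sides non-empty per stratum
}

#' Stratified, subject-aware 70/30 split
#'
#' Splits a feature table into training and testing parts, stratified by
#' group; when `group_aware`, whole subjects are assigned to one side so no
#' subject's epochs leak across the split.
#'
#' @param table A `feature_table` with a binary `group` column.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` feature tables.
#' @export
split_train_test <- function(table, spec = split_spec()) {
  groups <- sort(unique(table$group))
  if (length(groups) < 2L) stop("both classes must be present before splitting")
  with_local_seed(spec$seed, {
    if (spec$group_aware) {
      units <- unique(table[c("subject_id", "group")])
      if (any(table(units$group) < 2L)) {
        stop("need >= 2 subjects per class for a subject-disjoint split")
      }
      sizes <- table(units$group)
      n_train <- allocate_train(stats::setNames(as.integer(sizes), names(sizes)),
                                spec$train_fraction)
      train_ids <- unlist(lapply(groups, function(g) {
        ids <- sort(units$subject_id[units$group == g])
        sample(ids, n_train[[g]])
      }))
      tr <- table$subject_id %in% train_ids
    } else {
      idx <- seq_len(nrow(table))
      if (spec$stratified) {
        sizes <- table(table$group)
        n_train <- allocate_train(stats::setNames(as.integer(sizes), names(sizes)),
                                  spec$train_fraction)
        tr_idx <- unlist(lapply(groups, function(g) {
          sample(idx[table$group == g], n_train[[g]])
        }))
      } else {
        tr_idx <- sample(idx, round(spec$train_fraction * length(idx)))
      }
      tr <- idx %in% tr_idx
    }
    train <- table[tr, , drop = FALSE]
    test <- table[!tr, , drop = FALSE]
    for (part in list(train, test)) {
      if (length(unique(part$group)) < 2L) {
        stop("a class is absent from one side of the split; ",
             "consider per-epoch aggregation for a larger sample")
      }
    }
    list(train = train, test = test)
  })
}

#' Supported classifier families
#' @return Character vector of the four model-family identifiers.
#' @export
model_families <- function() {
  c("decision_tree", "svm_rbf", "logistic", "random_forest")
}

prepare_xy <- function(table, positive, label_col = "group") {
  feats <- setdiff(names(table), c(meta_columns(table), label_col))
  x <- as.matrix(table[feats])
  y <- factor(ifelse(table[[label_col]] == positive, "pos", "neg"),
              levels = c("neg", "pos"))
  list(x = x, y = y, features = feats)
}

impute_median <- function(x_train, x_test) {
  med <- apply(x_train, 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  fill <- function(m) {
    for (j in seq_len(ncol(m))) m[is.na(m[, j]), j] <- med[j]
    m
  }
  list(train = fill(x_train), test = fill(x_test))
}

#' Train one classifier family and score the test set
#'
#' Fits one of the four model families on the training table and returns a
#' continuous score in \[0, 1\] (class probability for the positive class,
#' stroke by default) plus hard labels at the 0.5 threshold for every test
#' row. Missing feature values are imputed by the training-set median. The
#' decision tree uses the entropy (information) split criterion; the RBF
#' SVM tunes cost/gamma by 10-fold cross-validation on the training set;
#' `random_forest` is a standard random forest; `logistic` is a binomial
#' GLM. All randomness is controlled by `seed`.
#'
#' @param train,test Feature tables (selected features plus metadata).
#' @param model_family One of [model_families()].
#' @param positive Positive-class label (default `"stroke"`).
#' @param label_col Metadata column holding the class label.
#' @param seed Integer seed.
#' @param svm_cv Folds for the SVM hyperparameter search (default 10).
#' @param svm_grid Named list with candidate `cost` and `gamma` values;
#'   gamma defaults are scalings of 1/p.
#' @return List: `scores` (numeric in \[0, 1\]), `labels` (factor
#'   `neg`/`pos`), `truth`, `model_family`.
#' @export
train_and_score <- function(train, test,
                            model_family = model_families(),
                            positive = "stroke", label_col = "group",
                            seed = 1L, svm_cv = 10,
                            svm_grid = NULL) {
  model_family <- match.arg(model_family)
  tr <- prepare_xy(train, positive, label_col)
  te <- prepare_xy(test, positive, label_col)
  if (nlevels(droplevels(tr$y)) < 2L) stop("training data has a single class")
  imp <- impute_median(tr$x, te$x)
  xtr <- imp$train; xte <- imp$test
  dtr <- data.frame(.y = tr$y, xtr, check.names = TRUE)
  dte <- data.frame(xte, check.names = TRUE)

  scores <- with_local_seed(seed, {
    switch(model_family,
      decision_tree = {
        fit <- rpart::rpart(.y ~ ., data = dtr, method = "class",
                            parms = list(split = "information"))
        predict(fit, dte, type = "prob")[, "pos"]
      },
      svm_rbf = {
        p <- ncol(xtr)
        if (is.null(svm_grid)) {
          svm_grid <- list(cost = c(1, 10), gamma = c(0.5, 1, 2) / p)
        }
        folds <- min(svm_cv, nrow(dtr))  # k-fold CV needs k <= n
        tuned <- e1071::tune(e1071::svm, .y ~ ., data = dtr,
                             kernel = "radial",
                             ranges = svm_grid,
                             tunecontrol = e1071::tune.control(cross = folds))
        fit <- e1071::svm(.y ~ ., data = dtr, kernel = "radial",
                          cost = tuned$best.parameters$cost,
                          gamma = tuned$best.parameters$gamma,
                          probability = TRUE)
        attr(predict(fit, dte, probability = TRUE), "probabilities")[, "pos"]
      },
      logistic = {
        fit <- suppressWarnings(
          stats::glm(.y ~ ., data = dtr, family = stats::binomial()))
        suppressWarnings(
          as.numeric(predict(fit, dte, type = "response")))
      },
      random_forest = {
        fit <- randomForest::randomForest(x = xtr, y = tr$y)
        predict(fit, xte, type = "prob")[, "pos"]
      }
    )
  })
  scores <- pmin(pmax(as.numeric(scores), 0), 1)
  list(
    scores = scores,
    labels = factor(ifelse(scores >= 0.5, "pos", "neg"),
                    levels = c("neg", "pos")),
    truth = te$y,
    model_family = model_family
  )
}

#' Confusion-matrix metric panel
#'
#' Computes the standard panel from hard predictions with the stroke group
#' as positive class: TP/TN/FP/FN counts, accuracy, sensitivity (TPR),
#' specificity (TNR), precision (PPV) and negative predictive value.
#' Division-by-zero cells yield `NA` markers.
#'
#' @param truth Factor/vector of true labels (`pos`/`neg`, or logical).
#' @param predictions Hard predicted labels, same encoding and length.
#' @return One-row data.frame of counts and metrics.
#' @export
confusion_metrics <- function(truth, predictions) {
  truth <- as_pos_neg(truth)
  predictions <- as_pos_neg(predictions)
  if (length(truth) != length(predictions)) {
    stop("truth and predictions must have the same length")
  }
  tp <- sum(truth == "pos" & predictions == "pos")
  tn <- sum(truth == "neg" & predictions == "neg")
  fp <- sum(truth == "neg" & predictions == "pos")
  fn <- sum(truth == "pos" & predictions == "neg")
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  data.frame(
    TP = tp, TN = tn, FP = fp, FN = fn,
    accuracy = sdiv(tp + tn, tp + tn + fp + fn),
    sensitivity = sdiv(tp, tp + fn),
    specificity = sdiv(tn, tn + fp),
    precision = sdiv(tp, tp + fp),
    npv = sdiv(tn, tn + fn)
  )
}

as_pos_neg <- function(x) {
  if (is.logical(x)) return(ifelse(x, "pos", "neg"))
  x <- as.character(x)
  map <- c(pos = "pos", neg = "neg", stroke = "pos", control = "neg",
           "TRUE" = "pos", "FALSE" = "neg", "1" = "pos", "0" = "neg",
           active = "pos", resting = "neg")
  if (!all(x %in% names(map))) stop("unrecognized class labels")
  unname(map[x])
}

#' AUC and Gini from continuous scores
#'
#' Area under the ROC curve by the rank (Mann-Whitney) estimator with
#' midrank tie correction, and the Gini coefficient `2 * AUC - 1`.
#'
#' @param truth True labels (positive = stroke).
#' @param scores Continuous scores, larger = more positive.
#' @return List with `auc` and `gini`; `NA` markers when only one class is
#'   present.
#' @export
auc_gini <- function(truth, scores) {
  truth <- as_pos_neg(truth)
  pos <- truth == "pos"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(list(auc = NA_real_, gini = NA_real_))
  r <- rank(scores)  # midranks handle ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(auc = auc, gini = 2 * auc - 1)
}

#' Empirical ROC curve points
#'
#' False-positive and true-positive rates at every score threshold,
#' suitable for plotting and for trapezoidal-area cross-checks against the
#' rank-based AUC.
#'
#' @inheritParams auc_gini
#' @return Data.frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(truth, scores) {
  truth <- as_pos_neg(truth)
  pos <- truth == "pos"
  n1 <- sum(pos); n0 <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

# Trapezoidal area under an ROC constructed by roc_points().
trapezoid_auc <- function(truth, scores) {
  pts <- roc_points(truth, scores)
  sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
}

#' Run the full classification experiment grid
#'
#' For each task-specific dataset (and the task-independent pooled
#' dataset `"all"`) and each requested model family: split 70/30
#' (subject-disjoint, stratified), select features on the training side by
#' chi-square importance, train, score the test set, and assemble the
#' metric panel (counts, accuracy, sensitivity, specificity, precision,
#' NPV, AUC, Gini). With `target = "active"` the label becomes
#' resting-versus-active (workload level > 0) with groups pooled.
#'
#' @param table A per-epoch or per-task `feature_table`.
#' @param tasks Task datasets to run (default all present plus `"all"`);
#'   ignored for `target = "active"`, which always pools tasks.
#' @param models Model families (default all four).
#' @param spec A [split_spec()].
#' @param target `"group"` (stroke vs control) or `"active"` (resting vs
#'   active states).
#' @param select_threshold Importance threshold for training-side feature
#'   selection (`NULL` to skip selection).
#' @param svm_cv,svm_grid Passed to [train_and_score()].
#' @return Data.frame, one row per (dataset, model): the metric panel plus
#'   test-set size; `roc` attribute holds per-(dataset, model) ROC points.
#' @export
run_experiment <- function(table, tasks = NULL, models = model_families(),
                           spec = split_spec(), target = c("group", "active"),
                           select_threshold = 0.95, svm_cv = 10,
                           svm_grid = NULL) {
  target <- match.arg(target)
  models <- match.arg(models, model_families(), several.ok = TRUE)
  if (target == "active") {
    tasks <- "all"
    table$active_label <- ifelse(table$workload_level > 0, "active", "resting")
    label_col <- "active_label"; positive <- "active"
  } else {
    label_col <- "group"; positive <- "stroke"
    if (is.null(tasks)) tasks <- c(sort(unique(table$task)), "all")
    missing_tasks <- setdiff(setdiff(tasks, "all"), unique(table$task))
    if (length(missing_tasks)) {
      stop("task(s) not present: ", paste(missing_tasks, collapse = ", "))
    }
  }
  if (length(tasks) == 0L) stop("empty task subset")
  rows <- list()
  rocs <- list()
  for (tk in tasks) {
    sub <- if (tk == "all") table else table[table$task == tk, , drop = FALSE]
    class(sub) <- class(table)
    halves <- split_train_test(sub, spec)
    train <- halves$train; test <- halves$test
    if (target == "active") {
      # keep the active label out of the feature columns
      sel_train <- train; sel_test <- test
    } else if (!is.null(select_threshold)) {
      screened <- screen_features(train)
      sel <- select_features(screened, select_threshold)
      keep <- c(meta_columns(train), setdiff(names(sel$table), meta_columns(train)))
      if (length(keep) == length(meta_columns(train))) {
        # nothing selected: fall back to the screened set
        keep <- names(screened)
      }
      sel_train <- train[keep]; sel_test <- test[keep]
      class(sel_train) <- class(train); class(sel_test) <- class(test)
    } else {
      sel_train <- train; sel_test <- test
    }
    for (mf in models) {
      res <- train_and_score(sel_train, sel_test, mf, positive = positive,
                             label_col = label_col, seed = spec$seed,
                             svm_cv = svm_cv, svm_grid = svm_grid)
      panel <- confusion_metrics(res$truth, res$labels)
      ag <- auc_gini(res$truth, res$scores)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(dataset = tk, model = mf, n_test = length(res$truth),
                   stringsAsFactors = FALSE),
        panel, data.frame(auc = ag$auc, gini = ag$gini))
      rocs[[paste(tk, mf, sep = ":")]] <- roc_points(res$truth, res$scores)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "roc") <- rocs
  out
}
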