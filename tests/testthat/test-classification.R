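test_that("70/30 split is stratified, subject-disjoint and reproducible", {
  tb <- gaussian_feature_table(n_subj_per_group = 5, epochs_per_subj = 6)
  sp <- split_spec(seed = 7)
  halves <- split_train_test(tb, sp)
  train_subj <- unique(halves$train$subject_id)
  test_subj <- unique(halves$test$subject_id)
  expect_length(train_subj, 7L)   # round(0.7 * 10)
  expect_length(test_subj, 3L)
  expect_length(intersect(train_subj, test_subj), 0L)
  expect_setequal(unique(halves$train$group), c("stroke", "control"))
  expect_setequal(unique(halves$test$group), c("stroke", "control"))

  halves2 <- split_train_test(tb, sp)
  expect_identical(halves, halves2)

  # epoch-level split without group awareness still stratifies
  sp2 <- split_spec(group_aware = FALSE, seed = 3)
  h3 <- split_train_test(tb, sp2)
  expect_equal(nrow(h3$train), round(0.7 * nrow(tb)))

  expect_error(split_train_test(tb[tb$group == "stroke", ], sp), "class")
})

test_that("every model family separates linearly separated features", {
  tb <- gaussian_feature_table(n_subj_per_group = 6, epochs_per_subj = 6,
                               n_features = 3, shift = 8, seed = 13)
  halves <- split_train_test(tb, split_spec(seed = 5))
  for (mf in model_families()) {
    res <- train_and_score(halves$train, halves$test, mf, seed = 11)
    panel <- confusion_metrics(res$truth, res$labels)
    expect_equal(panel$accuracy, 1.0)
    expect_true(all(res$scores >= 0 & res$scores <= 1))
  }
})

test_that("label-shuffled training data scores at chance AUC", {
  aucs <- vapply(1:20, function(s) {
    tb <- gaussian_feature_table(n_subj_per_group = 6, epochs_per_subj = 6,
                                 n_features = 4, shift = 0, seed = 500 + s)
    halves <- split_train_test(tb, split_spec(seed = s))
    res <- train_and_score(halves$train, halves$test, "decision_tree",
                           seed = s)
    auc_gini(res$truth, res$scores)$auc
  }, numeric(1))
  expect_equal(mean(aucs), 0.5, tolerance = 0.2)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("single-class training data is rejected", {
  tb <- gaussian_feature_table()
  tr <- tb[tb$group == "stroke", ]
  class(tr) <- class(tb)
  expect_error(train_and_score(tr, tb, "logistic"), "single class")
})

test_that("confusion metrics reproduce the formula panel", {
  # TP=45, FN=5, TN=40, FP=10
  truth <- c(rep("pos", 50), rep("neg", 50))
  pred <- c(rep("pos", 45), rep("neg", 5), rep("neg", 40), rep("pos", 10))
  m <- confusion_metrics(truth, pred)
  expect_equal(m[, c("TP", "FN", "TN", "FP")],
               data.frame(TP = 45L, FN = 5L, TN = 40L, FP = 10L))
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.80)
  expect_equal(m$precision, 45 / 55, tolerance = 1e-12)
  expect_equal(m$npv, 40 / 45, tolerance = 1e-12)
  expect_equal(m$accuracy, 0.85)

  perfect <- confusion_metrics(truth, truth)
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "npv")]) == 1))

  allpos <- confusion_metrics(truth, rep("pos", 100))
  expect_equal(allpos$sensitivity, 1.0)
  expect_equal(allpos$specificity, 0.0)
  expect_equal(allpos$accuracy, 0.5)
  expect_true(is.na(allpos$npv))  # TN + FN = 0

  # internal consistency: ACC = (sens*P + spec*N) / (P + N)
  set.seed(19)
  r_truth <- sample(c("pos", "neg"), 60, replace = TRUE)
  r_pred <- sample(c("pos", "neg"), 60, replace = TRUE)
  mm <- confusion_metrics(r_truth, r_pred)
  P <- sum(r_truth == "pos"); N <- sum(r_truth == "neg")
  expect_equal(mm$accuracy, (mm$sensitivity * P + mm$specificity * N) / (P + N))

  expect_error(confusion_metrics(truth, pred[1:10]), "length")
})

test_that("rank AUC agrees with the trapezoidal ROC area and pROC", {
  set.seed(23)
  for (i in 1:25) {
    n <- 40
    truth <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(truth)) < 2) next
    scores <- round(stats::runif(n), 2)  # coarse grid forces ties
    ag <- auc_gini(truth, scores)
    expect_equal(ag$auc, qeegstroke:::trapezoid_auc(truth, scores),
                 tolerance = 1e-9)
    expect_equal(ag$gini, 2 * ag$auc - 1, tolerance = 1e-12)
    # anti-learning flips the AUC
    expect_equal(auc_gini(truth, -scores)$auc, 1 - ag$auc, tolerance = 1e-9)
  }
  skip_if_not_installed("pROC")
  set.seed(29)
  truth <- sample(c("pos", "neg"), 80, replace = TRUE)
  scores <- stats::rnorm(80) + (truth == "pos")
  expect_equal(auc_gini(truth, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(truth, scores, levels = c("neg", "pos"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("AUC endpoints and degenerate labels behave", {
  truth <- c(rep("pos", 5), rep("neg", 5))
  expect_equal(auc_gini(truth, c(6:10, 1:5))$auc, 1.0)
  expect_equal(auc_gini(truth, c(6:10, 1:5))$gini, 1.0)
  expect_true(is.na(auc_gini(rep("pos", 4), 1:4)$auc))
})

test_that("the experiment grid covers datasets x models deterministically", {
  set.seed(37)
  tb <- gaussian_feature_table(n_subj_per_group = 6, epochs_per_subj = 8,
                               n_features = 3, shift = 2, seed = 61)
  # distribute epochs over the four tasks to build task datasets
  tasks <- task_labels()
  tb$task <- rep(tasks, length.out = nrow(tb))
  tb$workload_level <- unname(workload_levels()[tb$task])
  tb$epoch_index <- stats::ave(seq_len(nrow(tb)), tb$subject_id, tb$task,
                               FUN = seq_along)
  res <- run_experiment(tb, models = c("decision_tree", "logistic"),
                        spec = split_spec(seed = 2), select_threshold = NULL,
                        svm_cv = 3)
  expect_equal(nrow(res), 5 * 2)  # 4 tasks + pooled, 2 models
  expect_setequal(unique(res$dataset), c(tasks, "all"))
  expect_true(all(res$auc >= 0 & res$auc <= 1))
  expect_equal(res$gini, 2 * res$auc - 1, tolerance = 1e-12)

  res2 <- run_experiment(tb, models = c("decision_tree", "logistic"),
                         spec = split_spec(seed = 2), select_threshold = NULL,
                         svm_cv = 3)
  expect_identical(res, res2)

  expect_error(run_experiment(tb, tasks = character(0)), "empty task")
  expect_error(run_experiment(tb, tasks = "sleeping"), "not present")
})

test_that("resting-vs-active target pools groups and relabels epochs", {
  tb <- gaussian_feature_table(n_subj_per_group = 5, epochs_per_subj = 8,
                               n_features = 3, shift = 0, seed = 71)
  tasks <- task_labels()
  tb$task <- rep(tasks, length.out = nrow(tb))
  tb$workload_level <- unname(workload_levels()[tb$task])
  tb$epoch_index <- stats::ave(seq_len(nrow(tb)), tb$subject_id, tb$task,
                               FUN = seq_along)
  # make active epochs separable so the harness has signal
  tb$f01__feat__all <- tb$f01__feat__all + 4 * (tb$workload_level > 0)
  res <- run_experiment(tb, models = "decision_tree",
                        spec = split_spec(seed = 4), target = "active")
  expect_equal(nrow(res), 1L)
  # positive prevalence 0.75: 3 active tasks of 4
  expect_equal((res$TP + res$FN) / res$n_test, 0.75)
  expect_gt(res$accuracy, 0.9)
})
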