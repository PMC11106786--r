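# Evaluation suite: splits, folds, confusion matrices, classification
# reports (against an independent per-formula oracle), rank AUC, kappa and
# MCC.

test_that("stratified 70/30 split: sizes, disjointness, determinism", {
  labels <- c(rep("normal", 534), rep("tinnitus", 484))   # 1,018 ears
  sp <- split_train_test(labels, 0.30, seed = 1)
  expect_equal(length(sp$test), 305)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labels))
  expect_length(intersect(sp$train, sp$test), 0)
  # per-class counts follow the rounding rule
  expect_equal(sum(labels[sp$test] == "normal"), round(534 * 0.3))
  expect_equal(sum(labels[sp$test] == "tinnitus"), round(484 * 0.3))
  expect_identical(split_train_test(labels, 0.30, seed = 1), sp)
  expect_false(identical(split_train_test(labels, 0.30, seed = 2)$test,
                         sp$test))
  expect_error(split_train_test(labels, 1.2), class = "audiodx_config_error")
})

test_that("stratified k-fold: balanced class counts per fold", {
  labels <- c(rep("tinnitus", 242), rep("normal", 267))
  folds <- stratified_kfold(labels, k = 5, seed = 3)
  expect_setequal(unique(folds), 1:5)
  per_fold_tin <- table(folds[labels == "tinnitus"])
  expect_true(all(per_fold_tin %in% c(48, 49)))   # 242 = 5*48 + 2
  per_fold_all <- table(folds)
  expect_lte(max(per_fold_all) - min(per_fold_all), 2)
  expect_identical(stratified_kfold(labels, k = 5, seed = 3), folds)
  expect_error(stratified_kfold(c("a", "a", "b"), k = 3),
               class = "audiodx_cv_error")
})

test_that("confusion matrix matches a brute-force tally", {
  y_true <- c("normal", "tinnitus", "normal", "tinnitus", "tinnitus", "normal")
  y_pred <- c("normal", "normal", "tinnitus", "tinnitus", "tinnitus", "normal")
  cm <- confusion(y_true, y_pred)
  for (a in c("normal", "tinnitus")) {
    for (p in c("normal", "tinnitus")) {
      expect_equal(cm[a, p], sum(y_true == a & y_pred == p))
    }
  }
  expect_equal(sum(cm), 6)

  perfect <- confusion(y_true, y_true)
  expect_equal(perfect["normal", "tinnitus"] + perfect["tinnitus", "normal"],
               0)
  expect_error(confusion(c("normal", "weird"), c("normal", "normal")),
               class = "audiodx_metric_error")
})

# independent per-formula recomputation used as the report oracle
report_oracle <- function(cm) {
  sup <- rowSums(cm); prd <- colSums(cm); cor <- diag(cm)
  prec <- ifelse(prd == 0, 0, cor / prd)
  rec <- ifelse(sup == 0, 0, cor / sup)
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  list(precision = unname(prec), recall = unname(rec), f1 = unname(f1),
       support = unname(sup), accuracy = sum(cor) / sum(cm),
       macro_f1 = mean(f1),
       weighted_f1 = sum(f1 * sup) / sum(sup))
}

test_that("classification report equals the per-formula oracle on 100 random matrices", {
  withr::with_seed(99, {
    for (i in 1:100) {
      cm <- random_confusion()
      rep <- classification_report(cm)
      orc <- report_oracle(unclass(cm))
      expect_equal(rep$per_class$precision, orc$precision)
      expect_equal(rep$per_class$recall, orc$recall)
      expect_equal(rep$per_class$f1, orc$f1)
      expect_equal(rep$per_class$support, orc$support)
      expect_equal(rep$accuracy, orc$accuracy)
      expect_equal(unname(rep$macro_avg["f1"]), orc$macro_f1)
      expect_equal(unname(rep$weighted_avg["f1"]), orc$weighted_f1)
      # accuracy equals support-weighted recall
      expect_equal(rep$accuracy, unname(rep$weighted_avg["recall"]))
    }
  })
})

test_that("identity matrix gives all-ones metrics; zero rows flag zero-division", {
  rep <- classification_report(confusion_from_counts(10, 0, 0, 10))
  expect_true(all(rep$per_class$precision == 1))
  expect_true(all(rep$per_class$f1 == 1))
  expect_equal(rep$accuracy, 1)

  degen <- classification_report(confusion_from_counts(10, 0, 5, 0))
  expect_true(degen$zero_division)
  expect_equal(degen$per_class$precision[2], 0)
  expect_error(classification_report(confusion_from_counts(0, 0, 0, 0)),
               class = "audiodx_metric_error")
})

test_that("rank AUC: exact constants, perfect separation, tie half-credit", {
  y <- c(rep(1, 7), rep(0, 13))
  expect_identical(roc_auc(rep(0.42, 20), y), 0.5)
  expect_equal(roc_auc(c(rep(1, 7), rep(0, 13)), y), 1)
  expect_equal(roc_auc(c(rep(0, 7), rep(1, 13)), y), 0)
  # worked example: pairs (0.9 > 0.8) and (0.3 < 0.8) -> 1/2
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_error(roc_auc(c(1, 2), c(1, 1)), class = "audiodx_metric_error")
})

test_that("rank AUC equals the brute-force pairwise oracle and is monotone-invariant", {
  withr::with_seed(17, {
    for (i in 1:20) {
      n <- 30
      scores <- round(runif(n), 1)   # coarse grid forces ties
      y <- rbinom(n, 1, 0.5)
      if (length(unique(y)) < 2) next
      pos <- scores[y == 1]; neg <- scores[y == 0]
      pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      expect_equal(roc_auc(scores, y), mean(pairs))
      # strictly monotone transform leaves AUC unchanged
      expect_equal(roc_auc(exp(3 * scores) - 1, y), roc_auc(scores, y))
    }
  })
})

test_that("ROC points run monotonically from (0,0) to (1,1)", {
  withr::with_seed(5, {
    scores <- runif(40)
    y <- rbinom(40, 1, 0.5)
  })
  pts <- roc_points(scores, y)
  expect_equal(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_equal(c(pts$fpr[nrow(pts)], pts$tpr[nrow(pts)]), c(1, 1))
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
})

test_that("kappa and MCC: formula evaluation, perfect agreement, label symmetry", {
  cm <- confusion_from_counts(162, 9, 14, 118)
  # direct formula oracle
  n <- 303
  po <- 280 / n
  pe <- (171 * 176 + 132 * 127) / n^2
  expect_equal(cohen_kappa(cm), (po - pe) / (1 - pe), ignore_attr = TRUE)
  expect_equal(round(as.numeric(cohen_kappa(cm)), 3), 0.845)
  mcc_oracle <- (118 * 162 - 9 * 14) /
    sqrt(127) / sqrt(132) / sqrt(171) / sqrt(176)
  expect_equal(mcc(cm), mcc_oracle, ignore_attr = TRUE)
  expect_equal(round(as.numeric(mcc(cm)), 2), 0.85)

  perfect <- confusion_from_counts(50, 0, 0, 50)
  expect_equal(as.numeric(cohen_kappa(perfect)), 1)
  expect_equal(as.numeric(mcc(perfect)), 1)

  # swapping the label roles leaves the MCC magnitude unchanged
  swapped <- confusion_from_counts(118, 14, 9, 162)
  expect_equal(abs(as.numeric(mcc(swapped))), abs(as.numeric(mcc(cm))))

  degenerate <- confusion_from_counts(10, 0, 5, 0)
  expect_equal(as.numeric(mcc(degenerate)), 0)
  expect_true(attr(mcc(degenerate), "zero_division"))
})

test_that("metrics_report bundles everything consistently", {
  withr::with_seed(9, {
    y <- c(rep("normal", 30), rep("tinnitus", 30))
    scores <- ifelse(y == "tinnitus", runif(60, 0.3, 1), runif(60, 0, 0.7))
  })
  pred <- ifelse(scores >= 0.5, "tinnitus", "normal")
  mr <- metrics_report(y, pred, scores)
  expect_equal(sum(mr$confusion), 60)
  expect_equal(mr$auc, roc_auc(scores, y))
  expect_equal(mr$kappa, as.numeric(cohen_kappa(mr$confusion)))
  g <- glance(mr)
  expect_named(g, c("accuracy", "auc", "kappa", "mcc", "n"))
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(mr, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$accuracy, mr$report$accuracy)
})
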