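test_that("one-vs-rest counts match a brute-force pairwise tally", {
  expect_identical(confusion_counts(c("A", "A", "B"), c("A", "A", "B"), "A"),
                   list(tp = 2L, tn = 1L, fp = 0L, fn = 0L))
  expect_error(confusion_counts(c("A", "B"), "A", "A"), "same length")
  set.seed(99)
  for (i in 1:25) {
    n <- sample(5:60, 1)
    labs <- sample(LETTERS[1:4], 2 * n, replace = TRUE)
    truth <- labs[1:n]; pred <- labs[(n + 1):(2 * n)]
    target <- sample(LETTERS[1:4], 1)
    got <- confusion_counts(truth, pred, target)
    tally <- c(tp = 0L, tn = 0L, fp = 0L, fn = 0L)
    for (k in seq_len(n)) {
      cell <- if (truth[k] == target && pred[k] == target) "tp"
      else if (truth[k] == target) "fn"
      else if (pred[k] == target) "fp" else "tn"
      tally[cell] <- tally[cell] + 1L
    }
    expect_identical(unlist(got)[names(tally)], tally)
    expect_identical(sum(unlist(got)), n)
  }
})

test_that("class metrics reproduce hand-checked and degenerate tables", {
  m <- class_metrics(13, 53, 29, 5)
  expect_equal(round(unlist(m), 2),
               c(sensitivity = 0.72, specificity = 0.65, ppv = 0.31,
                 npv = 0.91, accuracy = 0.66, kappa = 0.24, f1 = 0.43))
  m <- class_metrics(0, 97, 2, 1)
  expect_identical(m$ppv, 0)
  expect_identical(m$f1, 0)
  expect_equal(round(m$kappa, 2), -0.01)
  m <- class_metrics(5, 0, 0, 0)
  expect_identical(c(m$sensitivity, m$accuracy, m$f1), c(1, 1, 1))
  # accuracy is invariant to swapping the roles of the two classes
  expect_identical(class_metrics(13, 53, 29, 5)$accuracy,
                   class_metrics(53, 13, 5, 29)$accuracy)
  expect_error(class_metrics(0, 0, 0, 0), "empty")
})

test_that("class metrics agree with caret's confusion matrix on random tables", {
  skip_if_not_installed("caret")
  set.seed(2024)
  for (i in 1:300) {
    cc <- as.list(stats::rmultinom(1, size = sample(4:200, 1),
                                   prob = stats::runif(4, 0.05, 1))[, 1])
    names(cc) <- c("tp", "fn", "fp", "tn")
    if (cc$tp + cc$fn == 0 || cc$tp + cc$fp == 0 || cc$fp + cc$tn == 0)
      next  # caret yields NA where this package uses the 0 convention
    got <- class_metrics(cc$tp, cc$tn, cc$fp, cc$fn)
    lv <- c("pos", "neg")
    ref <- caret::confusionMatrix(
      factor(c(rep("pos", cc$tp), rep("neg", cc$fn),
               rep("pos", cc$fp), rep("neg", cc$tn)), levels = lv),
      factor(c(rep("pos", cc$tp + cc$fn), rep("neg", cc$fp + cc$tn)),
             levels = lv),
      positive = "pos")
    expect_equal(got$sensitivity, unname(ref$byClass["Sensitivity"]), tolerance = 1e-12)
    expect_equal(got$specificity, unname(ref$byClass["Specificity"]), tolerance = 1e-12)
    expect_equal(got$ppv, unname(ref$byClass["Pos Pred Value"]), tolerance = 1e-12)
    if (cc$fn + cc$tn > 0)
      expect_equal(got$npv, unname(ref$byClass["Neg Pred Value"]), tolerance = 1e-12)
    expect_equal(got$accuracy, unname(ref$overall["Accuracy"]), tolerance = 1e-12)
    expect_equal(got$kappa, unname(ref$overall["Kappa"]), tolerance = 1e-12)
  }
})

test_that("macro F1 is the mean of unrounded per-class F1 values", {
  expect_identical(macro_f1(0.4), 0.4)
  expect_identical(macro_f1(c(0, 1)), 0.5)
  expect_error(macro_f1(numeric(0)), "no per-class")
  vc <- validation_counts()
  f1 <- vapply(seq_len(nrow(vc)),
               function(i) class_metrics(vc$tp[i], vc$tn[i], vc$fp[i], vc$fn[i])$f1,
               numeric(1))
  expect_equal(round(macro_f1(f1[vc$scheme == "eightfold"]), 2), 0.25)
  expect_equal(round(macro_f1(f1[vc$scheme == "threefold"]), 2), 0.68)
})

test_that("error summaries compute MSE and MAE on the step scale", {
  expect_identical(error_summary(c(1, 5, 8), c(1, 5, 8)), list(mse = 0, mae = 0))
  expect_identical(error_summary(c(2, 4), c(3, 1)), list(mse = 5, mae = 2))
  x <- c(1, 3, 6, 8)
  expect_identical(error_summary(x, x + 2), list(mse = 4, mae = 2))
  expect_error(error_summary(1:3, 1:2), "same length")
})

test_that("binary one-vs-rest kappa is symmetric between the two classes", {
  set.seed(5)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    truth <- sample(c("lt6", "ge6"), n, replace = TRUE)
    pred <- sample(c("lt6", "ge6"), n, replace = TRUE)
    k <- vapply(c("lt6", "ge6"), function(lb)
      class_metrics(confusion_counts(truth, pred, lb))$kappa, numeric(1))
    expect_equal(k[["lt6"]], k[["ge6"]], tolerance = 1e-12)
  }
})

test_that("per-class counts are coherent across the labels of a scheme", {
  set.seed(6)
  truth_scores <- sample(seq(1, 9.5, 0.5), 120, replace = TRUE)
  pred_steps <- sample(0:9, 120, replace = TRUE)
  ev <- pedss_evaluate(truth_scores, pred_steps, "eightfold")
  tab <- ev$table
  truth_lab <- edss_class(rescale_edss(truth_scores), "eightfold")
  pred_lab <- edss_class(impute_pedss(pred_steps), "eightfold")
  expect_identical(sum(tab$tp), sum(truth_lab == pred_lab))
  for (i in seq_len(nrow(tab)))
    expect_identical(tab$tp[i] + tab$fn[i], sum(truth_lab == tab$class[i]))
  # every metric row equals an independent recomputation
  for (i in seq_len(nrow(tab))) {
    cc <- confusion_counts(truth_lab, pred_lab, tab$class[i])
    m <- class_metrics(cc)
    expect_equal(tab$f1[i], m$f1)
    expect_equal(tab$kappa[i], m$kappa)
  }
  expect_equal(ev$macro_f1, mean(tab$f1))
})

test_that("evaluation is perfect under exact agreement and reproduces the published binary kappa", {
  scores <- c(rep(1, 3), 2.5, 3, 4.5, 5, 6, 6.5, 7, 8, 9.5)
  steps <- rescale_edss(scores)
  for (scheme in c("eightfold", "threefold", "binary")) {
    ev <- pedss_evaluate(scores, steps, scheme)
    expect_identical(ev$macro_f1, 1)
    expect_identical(ev$mse, 0)
    expect_identical(ev$mae, 0)
  }

  # label pattern with the published binary confusion structure:
  # 81 concordant low, 11 concordant severe, 2 low->severe, 6 severe->low
  truth <- c(rep(2.0, 81), rep(6.0, 11), rep(2.0, 2), rep(6.0, 6))
  pred <- c(rep(2L, 81), rep(7L, 11), rep(7L, 2), rep(2L, 6))
  ev <- pedss_evaluate(truth, pred, "binary")
  expect_identical(ev$table$tp, c(81L, 11L))
  expect_identical(ev$table$fp, c(6L, 2L))
  expect_equal(round(ev$table$kappa, 3), c(0.687, 0.687))
  expect_equal(round(ev$macro_f1, 2), 0.84)
})

test_that("published validation counts carry their printed margins", {
  vc <- validation_counts()
  expect_identical(nrow(vc), 13L)
  expect_true(all(vc$tp + vc$tn + vc$fp + vc$fn == 100L))
})
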