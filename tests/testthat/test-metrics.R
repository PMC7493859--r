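test_that("confusion counts follow the 2x2 table with ties positive", {
  cm <- confusion(c(0.9, 0.1), c(1, 0))
  expect_equal(unclass(cm), c(TP = 1L, FP = 0L, TN = 1L, FN = 0L))

  tie <- confusion(0.5, 1, threshold = 0.5)
  expect_equal(tie[["TP"]], 1L)

  set.seed(4)
  cm50 <- confusion(runif(50), rbinom(50, 1, 0.5))
  expect_equal(sum(cm50), 50L)
  expect_error(confusion(numeric(0), integer(0)), "empty")
})

test_that("perfect and inverted classifiers hit the metric extremes", {
  perfect <- structure(c(TP = 50L, FP = 0L, TN = 50L, FN = 0L),
                       class = "nucnet_confusion")
  expect_equal(accuracy(perfect), 1)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)
  expect_equal(mcc(perfect), 1)

  inverted <- structure(c(TP = 0L, FP = 50L, TN = 0L, FN = 50L),
                        class = "nucnet_confusion")
  expect_equal(accuracy(inverted), 0)
  expect_equal(mcc(inverted), -1)
})

test_that("metrics match direct formula evaluation on randomized tables", {
  set.seed(7)
  for (rep in 1:25) {
    counts <- c(TP = rpois(1, 30) + 1L, FP = rpois(1, 10),
                TN = rpois(1, 30) + 1L, FN = rpois(1, 10))
    tp <- counts["TP"]; fp <- counts["FP"]; tn <- counts["TN"]; fn <- counts["FN"]
    expect_equal(accuracy(counts), unname((tp + tn) / (tp + fp + tn + fn)))
    expect_equal(sensitivity(counts), unname(tp / (tp + fn)))
    expect_equal(specificity(counts), unname(tn / (tn + fp)))
    denom <- sqrt(prod(c(tn + fn, tn + fp, tp + fn, tp + fp)))
    if (denom > 0) {
      expect_equal(mcc(counts), unname((tp * tn - fp * fn) / denom))
    }
  }
})

test_that("the compatibility specificity formula divides by TN + FN", {
  counts <- c(TP = 40L, FP = 5L, TN = 45L, FN = 10L)
  expect_equal(specificity(counts), 45 / 50)
  expect_equal(specificity(counts, formula = "tn_fn"), 45 / 55)
})

test_that("degenerate confusion tables are handled explicitly", {
  no_neg <- c(TP = 10L, FP = 0L, TN = 0L, FN = 0L)
  expect_warning(val <- mcc(no_neg), "zero factor")
  expect_equal(val, 0)
  expect_error(accuracy(c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)), "all zero")
})

test_that("ROC AUC matches the exhaustive pairwise concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5))$auc, 0.5)

  scores <- c(0.8, 0.6, 0.55, 0.3); labels <- c(1, 0, 1, 0)
  expect_equal(roc_auc(scores, labels)$auc, pairwise_auc(scores, labels))

  set.seed(12)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    # coarse grid forces ties so the tie handling is exercised
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc, pairwise_auc(scores, labels))
  }
})

test_that("ROC curve spans (0,0) to (1,1) and AUC needs both classes", {
  r <- roc_auc(c(0.2, 0.7, 0.5), c(0, 1, 1))
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_error(roc_auc(c(0.1, 0.9), c(1, 1)), "both classes")
})

test_that("AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- runif(60)
  labels <- rbinom(60, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels)$auc, ref, tolerance = 1e-12)
})

test_that("label-swap maps AUC to its complement and MCC flips sign", {
  set.seed(9)
  scores <- runif(40); labels <- c(0, 1, rbinom(38, 1, 0.4))
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a)
  cm <- confusion(scores, labels)
  flipped <- structure(c(TP = cm[["FN"]], FP = cm[["TN"]],
                         TN = cm[["FP"]], FN = cm[["TP"]]),
                       class = "nucnet_confusion")
  expect_equal(suppressWarnings(mcc(flipped)), -suppressWarnings(mcc(cm)))
})
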