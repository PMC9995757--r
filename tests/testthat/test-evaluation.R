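test_that("one-vs-rest counts match hand enumeration and the partition identity", {
  # 3-unit hand case
  cc <- confusion_counts(c("a", "b", "a"), c("a", "a", "a"),
                         classes = c("a", "b"))
  expect_equal(unlist(cc[cc$class == "a", c("tp", "fp", "tn", "fn")]),
               c(tp = 2, fp = 0, tn = 0, fn = 1))
  expect_equal(unlist(cc[cc$class == "b", c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 1, tn = 2, fn = 0))

  # perfect agreement
  cc2 <- confusion_counts(rep("stand", 10), rep("stand", 10))
  expect_true(all(cc2$fp == 0) && all(cc2$fn == 0))

  # random instances: equality with brute force, rows sum to n,
  # sum of TP = number of correct units
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(5:50, 1)
      cls <- sample(activity_classes(), 4)
      pred <- sample(cls, n, replace = TRUE)
      truth <- sample(cls, n, replace = TRUE)
      got <- confusion_counts(pred, truth, classes = cls)
      ref <- counts_bruteforce(pred, truth, cls)
      expect_equal(as.data.frame(got), ref)
      expect_true(all(got$tp + got$fp + got$tn + got$fn == n))
      expect_equal(sum(got$tp), sum(pred == truth))
    }
  })

  expect_error(confusion_counts(c("a", "b"), "a"),
               class = "nearfallr_validation_error")
})

test_that("classification statistics implement the five ratios with NA on empty denominators", {
  st <- classification_stats(tibble::tibble(
    class = "stand", tp = 2323, fp = 54, tn = 11998, fn = 14))
  expect_equal(round(st$tpr, 6), 0.994009)
  expect_equal(round(st$acc, 6), 0.995274)

  nf <- classification_stats(tibble::tibble(
    class = "near_fall", tp = 58, fp = 5, tn = 14311, fn = 15))
  expect_equal(round(nf$tpr, 6), 0.794521)
  expect_equal(round(nf$ppv, 6), 0.920635)

  z <- classification_stats(tibble::tibble(
    class = "x", tp = 0, fp = 0, tn = 5, fn = 0))
  expect_true(is.na(z$tpr))
  expect_true(is.na(z$ppv))
  expect_equal(z$tnr, 1)
  expect_equal(z$acc, 1)

  expect_error(classification_stats(tibble::tibble(tp = -1, fp = 0,
                                                   tn = 0, fn = 0)),
               class = "nearfallr_validation_error")
})

test_that("trapezoid AUC equals pairwise concordance, including tied scores", {
  # perfectly separating scores
  expect_equal(roc_curve_auc(c(0.9, 0.8, 0.2, 0.1),
                             c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  # scores carrying no information
  expect_equal(roc_curve_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)

  # hand-listed pairs against explicit pair enumeration
  s <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  y <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_curve_auc(s, y)$auc, auc_concordance(s, y))

  # property: 100 random small instances with heavy ties
  withr::with_seed(123, {
    for (rep in 1:100) {
      n <- sample(4:50, 1)
      y <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(y) || !any(y)) y[1:2] <- c(TRUE, FALSE)
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
      expect_equal(roc_curve_auc(s, y)$auc, auc_concordance(s, y),
                   tolerance = 1e-12)
    }
  })

  expect_error(roc_curve_auc(c(0.1, 0.2), c(TRUE, TRUE)),
               class = "nearfallr_validation_error")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(7, {
    y <- sample(c(TRUE, FALSE), 80, replace = TRUE)
    s <- rnorm(80) + y
  })
  ours <- roc_curve_auc(s, y)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})
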