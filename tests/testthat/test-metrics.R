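# independent brute-force implementations used as oracles
bf_metrics <- function(tp, tn, fp, fn, beta = 1) {
  list(precision = tp / (tp + fp),
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       npv = tn / (tn + fn),
       accuracy = (tp + tn) / (tp + tn + fp + fn),
       f1 = 2 / (1 / (tp / (tp + fp)) + 1 / (tp / (tp + fn))),
       fbeta = (1 + beta^2) * tp / ((1 + beta^2) * tp + beta^2 * fn + fp))
}

rand_counts <- function() {
  repeat {
    v <- as.integer(sample(0:60, 4, replace = TRUE))
    # keep all ratios defined so the oracle comparison is exact
    if (v[1] + v[3] > 0 && v[1] + v[4] > 0 && v[2] + v[3] > 0 &&
        v[2] + v[4] > 0 && sum(v) > 0) return(v)
  }
}

test_that("confusion counts match an elementwise tally", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cc)[1:4], list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion(c(1, 0, 1, 0), c(0, 1, 0, 1))
  expect_equal(unclass(cc)[1:4], list(TP = 0L, TN = 0L, FP = 2L, FN = 2L))
  withr::with_seed(8, {
    lab <- sample(0:1, 200, replace = TRUE)
    pred <- sample(0:1, 200, replace = TRUE)
  })
  cc <- confusion(lab, pred)
  tally <- table(factor(lab, 0:1), factor(pred, 0:1))
  expect_equal(cc$TP, unname(tally["1", "1"]))
  expect_equal(cc$TN, unname(tally["0", "0"]))
  expect_equal(cc$FP, unname(tally["0", "1"]))
  expect_equal(cc$FN, unname(tally["1", "0"]))
  expect_error(confusion(1:3, 1:4), "equal length")
  expect_error(confusion(c(0, 2), c(0, 1)), "binary")
})

test_that("the metric formulas reproduce hand arithmetic", {
  m <- compute_metrics(structure(list(TP = 9, FP = 1, FN = 3, TN = 7,
                                      n = 20), class = "confusion_counts"))
  expect_equal(m$precision, 0.9)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(round(m$f1, 4), 0.8182)
  expect_equal(m$specificity, 7 / 8)
  expect_equal(m$npv, 0.7)
  expect_equal(m$accuracy, 0.8)
})

test_that("every metric matches the brute-force oracle on random tables", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      v <- rand_counts()
      cc <- structure(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4],
                           n = sum(v)), class = "confusion_counts")
      m <- compute_metrics(cc)
      o <- bf_metrics(v[1], v[2], v[3], v[4])
      for (k in c("precision", "sensitivity", "specificity", "npv",
                  "accuracy", "f1"))
        expect_equal(m[[k]], o[[k]], tolerance = 1e-12)
      b <- runif(1, 0.2, 5)
      expect_equal(f_beta(cc, b), bf_metrics(v[1], v[2], v[3], v[4], b)$fbeta,
                   tolerance = 1e-12)
      expect_equal(f_beta(cc, 1), m$f1, tolerance = 1e-12)
      expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
    }
  })
})

test_that("F0.5 favours precision and F2 favours recall", {
  withr::with_seed(13, {
    for (i in 1:200) {
      v <- rand_counts()
      cc <- structure(list(TP = v[1], TN = v[2], FP = v[3], FN = v[4],
                           n = sum(v)), class = "confusion_counts")
      m <- compute_metrics(cc)
      if (is.na(m$precision) || is.na(m$recall)) next
      if (m$precision > m$recall + 1e-9) {
        expect_gt(m$`f0.5`, m$f1); expect_gt(m$f1, m$f2)
      } else if (m$recall > m$precision + 1e-9) {
        expect_lt(m$`f0.5`, m$f1); expect_lt(m$f1, m$f2)
      }
    }
  })
  # precision == recall == r collapses every F-beta to r
  cc <- structure(list(TP = 30, TN = 50, FP = 10, FN = 10, n = 100),
                  class = "confusion_counts")
  m <- compute_metrics(cc)
  expect_equal(m$precision, m$recall)
  expect_equal(m$f1, 0.75)
  expect_equal(m$`f0.5`, 0.75)
  expect_equal(m$f2, 0.75)
})

test_that("undefined ratios are flagged, not silently zero", {
  cc <- confusion(c(1, 1, 1), c(0, 0, 0))  # nothing predicted positive
  m <- compute_metrics(cc)
  expect_true(is.na(m$precision))
  expect_true("precision" %in% m$undefined)
  expect_equal(m$sensitivity, 0)
})

test_that("AUPRC is 1 for a perfect ranker and rank-invariant", {
  lab <- c(rep(1, 5), rep(0, 5))
  p <- c(runif(5, 0.6, 1), runif(5, 0, 0.4))
  expect_equal(auprc(lab, p), 1)
  withr::with_seed(17, {
    lab <- sample(0:1, 60, replace = TRUE)
    p <- runif(60)
  })
  a1 <- auprc(lab, p)
  expect_equal(auprc(lab, qnorm(p / 2 + 0.25)), a1, tolerance = 1e-12)
  expect_equal(auprc(lab, 100 * p - 3), a1, tolerance = 1e-12)
  expect_true(a1 >= 0 && a1 <= 1)
  # random scores on balanced labels hover near the positive prevalence
  expect_lt(abs(a1 - mean(lab)), 0.2)
})

test_that("cross-validation evaluation pools and splits by fold", {
  fv <- shared_features()
  cv <- cross_validate(fv, spec = constant_spec(1L), k = 5, seed = 9)
  ev <- evaluate_cv(cv)
  expect_equal(ev$pooled$accuracy, 0.5)
  expect_equal(ev$pooled$sensitivity, 1)  # constant-1 retrieves all targets
  expect_true(is.na(ev$pooled$npv))       # and never predicts negative
  expect_equal(nrow(ev$per_fold), 5)
  df <- as.data.frame(ev$pooled)
  expect_equal(names(df)[1:3], c("Accuracy", "F1", "Precision"))
})
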