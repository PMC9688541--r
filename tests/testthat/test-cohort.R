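test_that("outcome labelling follows the diagnosis-transition rule", {
  expect_true(label_outcome("UWS", "MCS+")$improved)
  expect_true(label_outcome("UWS", "MCS-")$improved)
  expect_true(label_outcome("MCS-", "MCS+")$improved)
  expect_false(label_outcome("UWS", "UWS")$improved)
  expect_false(label_outcome("MCS-", "MCS-")$improved)
  expect_error(label_outcome("MCS+", "MCS+"), "unknown pre-experiment")
  expect_error(label_outcome("UWS", "awake"), "unknown follow-up")
  expect_true(label_outcome("UWS", "UWS", etiology = "CVD")$nontraumatic)
  expect_false(label_outcome("UWS", "UWS", etiology = "TBI")$nontraumatic)
  expect_error(label_outcome("UWS", "UWS", etiology = "stroke"), "etiology")
})

test_that("cohort summary counts outcomes, etiologies and ages", {
  rec <- load_patient_table()
  s <- summarize_cohort(rec)
  expect_equal(s$n, 18)
  expect_equal(s$n_improved, 10)
  expect_equal(s$n_not_improved, 8)
  expect_equal(s$n_tbi, 10)
  expect_equal(s$n_tbi_improved, 6)
  expect_equal(round(s$age_mean, 2), 36.56)
  expect_equal(round(s$age_sd, 2), 10.83)
  expect_error(summarize_cohort(rec[0, ]), "at least one")
})

test_that("pooled t-test handles identical and degenerate groups", {
  x <- c(1, 2, 3, 4)
  gt <- group_ttest(x, x)
  expect_equal(gt$t, 0)
  expect_equal(gt$p, 1)
  expect_equal(gt$df, 6)
  d <- group_ttest(c(2, 2), c(2, 2))
  expect_true(d$degenerate)
  expect_equal(d$p, 1)
  d2 <- group_ttest(c(3, 3), c(2, 2))
  expect_true(d2$degenerate)
  expect_equal(d2$p, 0)
  expect_error(group_ttest(1, c(1, 2)), "at least two")
})

test_that("pooled t-test p agrees with a permutation oracle", {
  withr::with_seed(23, {
    a <- rnorm(30, 0.3)
    b <- rnorm(30, 0)
  })
  gt <- group_ttest(a, b)
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  withr::with_seed(24, {
    perm <- replicate(20000, {
      g <- sample(60, 30)
      abs(mean(pooled[g]) - mean(pooled[-g]))
    })
  })
  p_perm <- mean(perm >= obs - 1e-12)
  # Monte-Carlo SE ~ sqrt(p(1-p)/2e4) plus the t-vs-permutation gap
  expect_lt(abs(gt$p - p_perm), 0.02)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(adj, 1)
    out
  }
  withr::with_seed(31, {
    for (i in 1:500) {
      p <- runif(sample(1:12, 1))
      a <- fdr_adjust(p)
      expect_equal(a, bh_oracle(p), tolerance = 1e-12)
      expect_true(all(a >= p - 1e-12) && all(a <= 1))
    }
  })
})

test_that("Gaussian fits use the sample SD and flag degeneracy", {
  g <- fit_gaussian(c(1, 3))
  expect_equal(g$mean, 2)
  expect_equal(g$sd, sqrt(2))
  expect_equal(g$density(2), dnorm(2, 2, sqrt(2)))
  expect_true(fit_gaussian(rep(0, 4))$degenerate)
  expect_error(fit_gaussian(5), "at least two")
  withr::with_seed(41, x <- rnorm(1e5, 5, 2))
  g <- fit_gaussian(x)
  expect_lt(abs(g$mean - 5) / 5, 0.01)
  expect_lt(abs(g$sd - 2) / 2, 0.01)
})

test_that("correlation is exact on a line and affine-invariant", {
  rec <- load_patient_table()
  acc <- 2 * rec$crsr_after_total + 1
  cr <- accuracy_crsr_correlation(rec, acc)
  expect_equal(cr$r, 1)
  expect_equal(cr$slope, 2)
  expect_equal(cr$intercept, 1)
  tab <- load_accuracy_table("cnn")
  r1 <- accuracy_crsr_correlation(rec, tab$accuracy_pct)$r
  r2 <- accuracy_crsr_correlation(rec, tab$accuracy_pct / 100)$r
  r3 <- accuracy_crsr_correlation(rec, 3 * tab$accuracy_pct + 7)$r
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)
  expect_error(accuracy_crsr_correlation(rec, rep(1, 18)), "zero variance")
  expect_error(accuracy_crsr_correlation(rec, 1:5), "one accuracy per")
})

test_that("the study report reproduces the published group structure", {
  rec <- load_patient_table()
  for (m in c("cnn", "bayesian")) {
    tab <- load_accuracy_table(m)
    st <- run_study_statistics(rec,
                               setNames(tab$accuracy_pct, tab$patient_id),
                               setNames(tab$f1, tab$patient_id), method = m)
    cmp <- st$comparisons
    expect_named(cmp, c("accuracy_outcome", "f1_outcome",
                        "accuracy_etiology", "f1_etiology"))
    # improved > not improved and TBI > NTBI, on accuracy and F1 alike
    for (ct in cmp) {
      expect_gt(ct$means[1], ct$means[2])
      expect_lt(ct$p, 0.05)
      expect_gte(ct$p_fdr, ct$p)
      expect_lte(ct$p_fdr, 1)
    }
    expect_equal(st$gaussians$improved$n, 10)
    expect_equal(st$gaussians$tbi$n, 10)
    expect_equal(st$correlation$n, 18)
  }
  expect_error(run_study_statistics(rec, setNames(1:17, rec$patient_id[1:17]),
                                    setNames(rep(1, 18), rec$patient_id)),
               "missing accuracy")
})
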