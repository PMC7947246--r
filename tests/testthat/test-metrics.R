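test_that("compute_metrics reproduces the worked examples", {
  # implied test confusion matrix of the source study (33 RVOT / 9 LVOT)
  r <- compute_metrics(confusion_counts(tp = 32, fn = 1, fp = 0, tn = 9))
  expect_equal(r$acc, 97.62)
  expect_equal(r$se, 96.97)
  expect_equal(r$sp, 100.00)
  expect_equal(r$f1_positive, 98.46)

  perfect <- compute_metrics(confusion_counts(10, 0, 0, 5))
  expect_true(all(unlist(perfect[c("acc", "se", "sp", "f1_positive")]) == 100))

  even <- compute_metrics(confusion_counts(1, 1, 1, 1))
  expect_true(all(unlist(even[c("acc", "se", "sp", "f1_positive")]) == 50))

  # zero denominators are NA, never 0
  no_pos <- compute_metrics(confusion_counts(0, 0, 2, 8))
  expect_true(is.na(no_pos$se))
})

test_that("accuracy is the prevalence-weighted mean of SE and SP", {
  set.seed(2)
  for (i in 1:20) {
    cc <- confusion_counts(sample(0:30, 1) + 1, sample(0:10, 1),
                           sample(0:10, 1), sample(0:30, 1) + 1)
    r <- compute_metrics(cc)
    n_pos <- cc$tp + cc$fn; n_neg <- cc$fp + cc$tn
    expect_equal(r$acc,
                 round((n_pos * r$se + n_neg * r$sp) / (n_pos + n_neg), 2),
                 tolerance = 0.02)
  }
})

test_that("roc_auc handles order, ties, chance level and monotone transforms", {
  y <- rep(c("LVOT", "RVOT"), each = 5)
  expect_equal(roc_auc(c(1:5 / 10, 6:10 / 10), y)$auc, 100)
  expect_equal(roc_auc(rep(0.5, 10), y)$auc, 50)
  expect_error(roc_auc(1:5, rep("RVOT", 5)), "degenerate-labels")

  set.seed(3)
  s <- runif(2000); yl <- sample(rep(c("RVOT", "LVOT"), 1000))
  a <- roc_auc(s, yl)$auc
  expect_gt(a, 47); expect_lt(a, 53)
  # strictly monotone transform leaves the AUC unchanged
  expect_equal(roc_auc(qlogis(s), yl)$auc, a)
})

test_that("bootstrap_ci is seeded, degenerate-safe and exact when forced", {
  y <- rep(c(1, 0), each = 10)
  s <- c(rep(0.9, 10), rep(0.1, 10))
  acc <- function(ss, yy) 100 * mean((ss >= 0.5) == (yy == 1))
  ci <- bootstrap_ci(acc, s, y, n_boot = 200, seed = 4)
  expect_equal(as.numeric(ci), c(100, 100))
  ci2 <- bootstrap_ci(acc, s, y, n_boot = 200, seed = 4)
  expect_identical(ci, ci2)
  expect_gte(attr(ci, "n_skipped"), 0)
})

test_that("fast DeLong variance equals the pairwise oracle (n <= 50)", {
  set.seed(6)
  for (i in 1:25) {
    n1 <- sample(5:25, 1); n0 <- sample(5:25, 1)
    s <- c(rnorm(n1, 1), rnorm(n0))
    if (i %% 3 == 0) s <- round(s, 1)  # force ties
    y <- rep(c(1, 0), c(n1, n0))
    ci <- auc_ci_delong(s, y)
    expect_equal(attr(ci, "var"), oracle_delong_var(s, y), tolerance = 1e-12)
    expect_gte(attr(ci, "auc"), ci[1L])
    expect_lte(attr(ci, "auc"), ci[2L])
  }
})

test_that("a perfectly separated AUC has a degenerate [100, 100] interval", {
  y <- rep(c(1, 0), each = 10)
  s <- c(rnorm(10, 10), rnorm(10, -10))
  ci <- auc_ci_delong(s, y)
  expect_equal(as.numeric(ci), c(100, 100))
})

test_that("delong_test is symmetric and exact under identity", {
  set.seed(7)
  y <- rep(c(1, 0), each = 30)
  a <- rnorm(60, y); b <- rnorm(60, y * 0.5)
  same <- delong_test(a, a, y)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delong_test(a, b[-1], y), "unpaired-scores")
})

test_that("evaluate_scores writes deterministic JSON", {
  set.seed(8)
  y <- rep(c("RVOT", "LVOT"), c(30, 12))
  s <- plogis(rnorm(42, ifelse(y == "RVOT", 2, -2)))
  r <- evaluate_scores(s, y, threshold = 0.5, n_boot = 300, seed = 2)
  expect_true(r$ci$acc[1L] <= r$acc && r$acc <= r$ci$acc[2L])
  p1 <- file.path(tempdir(), "m1.json"); p2 <- file.path(tempdir(), "m2.json")
  write_metrics_json(r, p1)
  write_metrics_json(evaluate_scores(s, y, threshold = 0.5, n_boot = 300,
                                     seed = 2), p2)
  expect_identical(readLines(p1), readLines(p2))
})
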