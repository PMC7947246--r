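test_that("split_cohort reproduces the published cohort sizes", {
  labels <- c(rep("RVOT", 323), rep("LVOT", 97))  # 77% RVOT of 420
  s <- split_cohort(labels, c(0.81, 0.09, 0.10), seed = 3)
  expect_equal(vapply(s, length, 0L),
               c(train = 340L, validation = 38L, test = 42L))
  expect_identical(s, split_cohort(labels, c(0.81, 0.09, 0.10), seed = 3))
})

test_that("split_cohort partitions exhaustively for any seed", {
  labels <- rep(c("RVOT", "LVOT"), c(70, 30))
  for (seed in 1:10) {
    s <- split_cohort(labels, seed = seed)
    all_idx <- sort(c(s$train, s$validation, s$test))
    expect_identical(all_idx, seq_along(labels))
    expect_equal(anyDuplicated(unlist(s)), 0L)
  }
  expect_error(split_cohort(rep("RVOT", 50)), "degenerate-cohort")
})

test_that("training separates separable clouds and is deterministic", {
  cl <- make_clouds()
  b <- train(cl$X, cl$labels, gbt_params(nrounds = 50), seed = 1)
  pr <- predict(b, cl$X)
  expect_equal(mean(pr$label == cl$labels), 1.0)
  b2 <- train(cl$X, cl$labels, gbt_params(nrounds = 50), seed = 1)
  expect_identical(predict(b2, cl$X)$score, pr$score)

  bad <- cl$X; bad[1, 1] <- NaN
  expect_error(train(bad, cl$labels), "bad-features")
})

test_that("shuffled labels give chance-level held-out AUC", {
  set.seed(5)
  X <- matrix(rnorm(200 * 12), 200, 12)
  colnames(X) <- paste0("f", 1:12)
  y <- sample(rep(c("RVOT", "LVOT"), each = 100))
  b <- train(X, y, gbt_params(nrounds = 40), seed = 1)
  Xnew <- matrix(rnorm(400 * 12), 400, 12)
  colnames(Xnew) <- colnames(X)
  ynew <- sample(rep(c("RVOT", "LVOT"), each = 200))
  auc <- roc_auc(predict(b, Xnew)$score, ynew)$auc
  expect_gt(auc, 40); expect_lt(auc, 60)
})

test_that("TreeSHAP equals the exhaustive Shapley oracle on one small tree", {
  set.seed(8)
  X <- matrix(rnorm(60 * 3), 60, 3)
  colnames(X) <- c("a", "b", "c")
  y <- ifelse(X[, 1] + 0.5 * X[, 2] > 0, "RVOT", "LVOT")
  b <- train(X, y, gbt_params(nrounds = 1, max_depth = 3), seed = 1)
  expect_equal(length(b$ensemble$trees), 1L)
  phi <- shap_values(b, X)
  tree <- b$ensemble$trees[[1L]]
  for (i in c(1, 13, 37)) {
    expect_equal(unname(phi[i, ]), oracle_tree_shap(tree, X[i, ]),
                 tolerance = 1e-10)
  }
})

test_that("SHAP attributions are additive for the full ensemble", {
  cl <- make_clouds(n_per = 60, p = 6)
  b <- train(cl$X, cl$labels, gbt_params(nrounds = 30), seed = 1)
  phi <- shap_values(b, cl$X)
  margin <- log(predict(b, cl$X)$score / (1 - predict(b, cl$X)$score))
  expect_equal(rowSums(phi) + attr(phi, "expected_value"), margin,
               tolerance = 1e-8)
})

test_that("SHAP selection drops constants, keeps informative features", {
  set.seed(9)
  n <- 160
  f1 <- rnorm(n); f2 <- rnorm(n)
  y <- ifelse(f1 + f2 > 0, "RVOT", "LVOT")
  X <- cbind(f1 = f1, f2 = f2, const = rep(1, n))
  b <- train(X, y, gbt_params(nrounds = 30), seed = 1)
  b2 <- select_features_by_shap(b, X, y)
  expect_true(all(c("f1", "f2") %in% b2$retained_features))
  expect_false("const" %in% b2$retained_features)
  expect_lte(length(b2$retained_features), ncol(X))
  expect_s3_class(b2$shap_report, "data.frame")
  # refit on retained features does not lose training accuracy materially
  acc1 <- mean(predict(b, X)$label == y)
  acc2 <- mean(predict(b2, X)$label == y)
  expect_gte(acc2, acc1 - 0.02)

  Xc <- cbind(c1 = rep(1, 20), c2 = rep(2, 20))
  yc <- rep(c("RVOT", "LVOT"), 10)
  bc <- train(Xc, yc, gbt_params(nrounds = 5), seed = 1)
  expect_error(select_features_by_shap(bc, Xc, yc), "no-informative-features")
})

test_that("choose_threshold maximizes Youden's J with the documented ties", {
  cl <- make_clouds(n_per = 30, p = 2)
  bundle <- train(cl$X, cl$labels, gbt_params(nrounds = 20), seed = 1)
  val <- make_clouds(n_per = 10, p = 2, seed = 2)
  bundle <- choose_threshold(bundle, val$X, val$labels)
  s <- predict(bundle, val$X)$score
  y <- as.integer(val$labels == "RVOT")
  j_at <- function(t) mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1
  # threshold attains the best J over an exhaustive cut scan
  grid <- sort(unique(c(s - 1e-9, s + 1e-9, 0.5)))
  expect_gte(j_at(bundle$threshold), max(vapply(grid, j_at, 0)) - 1e-9)

  # perfect separation: threshold lies strictly inside the score gap
  if (min(s[y == 1]) > max(s[y == 0])) {
    expect_gt(bundle$threshold, max(s[y == 0]))
    expect_lt(bundle$threshold, min(s[y == 1]))
  }

  expect_error(choose_threshold(bundle, val$X, rep("RVOT", 20)),
               "degenerate-validation")
})

test_that("prediction is boundary-inclusive and name-keyed", {
  cl <- make_clouds(n_per = 40, p = 4)
  b <- train(cl$X, cl$labels, gbt_params(nrounds = 20), seed = 1)
  s <- predict(b, cl$X)$score
  b$threshold <- s[1L]
  expect_equal(predict(b, cl$X)$label[1L], "RVOT")  # score == threshold
  # column order does not matter
  perm <- cl$X[, c(3, 1, 4, 2)]
  expect_identical(predict(b, perm)$score, s)
  expect_error(predict(b, cl$X[, 1:2]), "missing-feature")
})

test_that("model bundles survive a save/load round trip", {
  cl <- make_clouds(n_per = 30, p = 3)
  b <- train(cl$X, cl$labels, gbt_params(nrounds = 10), seed = 1)
  dir <- file.path(tempdir(), "bundle")
  save_model_bundle(b, dir)
  b2 <- load_model_bundle(dir)
  expect_equal(predict(b2, cl$X)$score, predict(b, cl$X)$score,
               tolerance = 1e-12)
  expect_equal(b2$threshold, b$threshold)
})
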