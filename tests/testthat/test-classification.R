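test_that("well-separated classes classify perfectly (brute-force verified)", {
  df <- gaussian_features(n_per_class = 600, delta = 4, seed = 3)
  x <- as.matrix(df[, 1:8])
  # separability oracle: enumerate thresholds on the difference-of-means
  # projection; a perfect split must exist before asserting perfection
  dirvec <- colMeans(x[df$label == "MM", ]) - colMeans(x[df$label == "BN", ])
  proj <- drop(x %*% dirvec)
  expect_gt(min(proj[df$label == "MM"]), max(proj[df$label == "BN"]))
  rep <- cross_validate(df, cv_config(seed = 5))
  expect_equal(rep$overall_accuracy, 1)
  expect_equal(rep$mean_auc, 1)
  expect_equal(rep$auc_sd, 0)
  expect_true(all(rep$fold_aucs == 1))
})

test_that("uninformative constant features give chance-level AUC", {
  df <- gaussian_features(n_per_class = 100, p = 2, seed = 9)
  df$mean_b <- 1; df$sd_b <- 1  # identical constants, balanced labels
  rep <- cross_validate(df, cv_config(feature_subset = c("mean_b", "sd_b"),
                                      seed = 2))
  expect_equal(rep$mean_auc, 0.5, tolerance = 1e-9)  # all scores tie
})

test_that("per-fold AUC equals the Mann-Whitney rank-sum statistic", {
  df <- small_dataset(n_per_class = 1, n_ascans = 150, seed = 11)
  rep <- cross_validate(df, cv_config(seed = 13))
  for (k in seq_len(10)) {
    sel <- rep$predictions$fold == k
    oracle <- rank_sum_auc(rep$predictions$score[sel],
                           rep$predictions$label[sel] == "MM")
    expect_equal(rep$fold_aucs[k], oracle, tolerance = 1e-12)
  }
})

test_that("folds partition the data evenly and respect stratification", {
  df <- gaussian_features(n_per_class = 105, p = 2, seed = 4)
  rep <- cross_validate(df, cv_config(seed = 1,
                                      feature_subset = c("mean_b", "sd_b")))
  fold <- rep$predictions$fold
  expect_identical(sort(unique(fold)), 1:10)
  sizes <- table(fold)
  expect_lte(diff(range(sizes)), 1)
  per_class <- table(fold, rep$predictions$label)
  expect_lte(max(abs(per_class[, "MM"] - per_class[, "BN"])), 2)
  expect_identical(length(fold), 210L)  # every row in exactly one test fold
})

test_that("reports are deterministic given the seed", {
  df <- small_dataset(n_per_class = 1, n_ascans = 100, seed = 23)
  r1 <- cross_validate(df, cv_config(seed = 7))
  r2 <- cross_validate(df, cv_config(seed = 7))
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$mean_roc, r2$mean_roc)
  r3 <- cross_validate(df, cv_config(seed = 8))
  expect_false(identical(r1$predictions$fold, r3$predictions$fold))
})

test_that("mean interpolated ROC is monotone on the 101-point grid", {
  df <- small_dataset(n_per_class = 1, n_ascans = 100, seed = 37)
  rep <- cross_validate(df, cv_config(seed = 3))
  expect_length(rep$mean_roc$fpr_grid, 101)
  expect_true(all(diff(rep$mean_roc$mean_tpr) >= 0))
  expect_equal(rep$mean_roc$mean_tpr[c(1, 101)], c(0, 1))
  expect_true(all(rep$fold_aucs >= 0 & rep$fold_aucs <= 1))
})

test_that("single-class input and unknown features are rejected", {
  df <- gaussian_features(n_per_class = 50, p = 2, seed = 2)
  df_one <- df[df$label == "BN", ]
  expect_error(cross_validate(df_one, cv_config()), "both classes")
  expect_error(cross_validate(df, cv_config(feature_subset = "nope")),
               "unknown feature")
  expect_error(cv_config(kernel = "rbf"), "unsupported kernel")
})

test_that("per-sample report reproduces correct/total arithmetic", {
  pred <- c(rep("MM", 90), rep("BN", 110), rep("MM", 200))
  truth <- c(rep("MM", 200), rep("MM", 200))
  ids <- rep(c("06_Melanoma", "04_Melanoma"), each = 200)
  rep <- per_sample_report(pred, ids, truth)
  r6 <- rep[rep$sample_id == "06_Melanoma", ]
  expect_identical(r6$correct, 90L)
  expect_equal(r6$proportion, 0.45)
  expect_false(r6$majority_correct)
  r4 <- rep[rep$sample_id == "04_Melanoma", ]
  expect_equal(r4$proportion, 1)
  expect_true(r4$majority_correct)
  # zero-correct boundary
  rep0 <- per_sample_report(rep("BN", 5), rep("s", 5), rep("MM", 5))
  expect_equal(rep0$proportion, 0)
})

test_that("label flip flips every weight sign", {
  df <- gaussian_features(n_per_class = 80, p = 4, seed = 6, delta = 1)
  x <- as.matrix(df[, 1:4])
  m1 <- svm_linear(x, df$label)
  flipped <- ifelse(df$label == "MM", "BN", "MM")
  m2 <- svm_linear(x, flipped)
  expect_equal(m2$weights, -m1$weights, tolerance = 1e-6)
  expect_equal(m2$bias, -m1$bias, tolerance = 1e-6)
})

test_that("duplicated feature shares the discriminative direction", {
  df <- gaussian_features(n_per_class = 150, p = 3, seed = 8, delta = 2)
  x <- as.matrix(df[, 1:3])
  m0 <- svm_linear(x, df$label)
  x2 <- cbind(x, dup = x[, 1])
  m1 <- svm_linear(x2, df$label)
  w0 <- m0$weights[[1]]
  expect_identical(sign(m1$weights[[1]]), sign(w0))
  expect_identical(sign(m1$weights[[4]]), sign(w0))
  expect_equal(m1$weights[[1]], m1$weights[[4]], tolerance = 0.05)
  # halved effective regularization stretches the shared weight at most ~2x
  expect_gt(abs(m1$weights[[1]] + m1$weights[[4]]), 0.5 * abs(w0))
  expect_lt(abs(m1$weights[[1]] + m1$weights[[4]]), 2 * abs(w0))
})

test_that("pure-noise feature gets the smallest weight at large n", {
  df <- gaussian_features(n_per_class = 1000, p = 4, seed = 10, delta = 1.5,
                          informative = c(TRUE, TRUE, TRUE, FALSE))
  rep <- cross_validate(df, cv_config(seed = 1,
                                      feature_subset = names(df)[1:4]))
  w <- abs(rep$weights)
  expect_lt(w[["sd_r2"]], min(w[1:3]))
})

test_that("weight extraction requires a linear kernel and sorts by size", {
  df <- gaussian_features(n_per_class = 60, p = 3, seed = 12)
  m <- svm_linear(as.matrix(df[, 1:3]), df$label)
  w <- extract_weights(m)
  expect_true(all(diff(abs(w)) <= 0))
  m$kernel <- "rbf"
  expect_error(extract_weights(m), "linear kernel")
})
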