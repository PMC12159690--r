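test_that("lower-triangle vectorization follows the row-major contract", {
  z3 <- matrix(0, 3, 3)
  z3[2, 1] <- z3[1, 2] <- 1
  z3[3, 1] <- z3[1, 3] <- 2
  z3[3, 2] <- z3[2, 3] <- 3
  expect_equal(vectorize_lower_triangle(z3), c(1, 2, 3))
  # row-major, not column-major: for m = 4 position 4 is (4,1) not (3,2)
  z4 <- matrix(0, 4, 4)
  vals <- c("21" = 1, "31" = 2, "32" = 3, "41" = 4, "42" = 5, "43" = 6)
  z4[2, 1] <- 1; z4[3, 1] <- 2; z4[3, 2] <- 3
  z4[4, 1] <- 4; z4[4, 2] <- 5; z4[4, 3] <- 6
  z4 <- z4 + t(z4)
  expect_equal(vectorize_lower_triangle(z4), as.numeric(vals))
  # length m(m-1)/2 at the atlas scale
  expect_length(vectorize_lower_triangle(random_symmetric(83)), 3403)
})

test_that("vector / matrix reconstruction round-trips", {
  z <- random_symmetric(7, seed = 2)
  v <- vectorize_lower_triangle(z)
  expect_equal(lower_triangle_matrix(v), z, ignore_attr = TRUE)
  expect_error(lower_triangle_matrix(1:4), "m\\(m-1\\)/2")
})

test_that("feature construction produces the documented shapes", {
  devs <- lapply(1:8, function(i) as_deviation(random_symmetric(6, seed = i) * 3,
                                               id = paste0("s", i)))
  fs_e <- deviation_features(devs, rep(c("a", "b"), each = 4), kind = "edges")
  expect_equal(dim(fs_e$X), c(8, 15))
  fs_r <- deviation_features(devs, rep(c("a", "b"), each = 4), kind = "red")
  expect_equal(dim(fs_r$X), c(8, 6))
  expect_error(deviation_features(devs, rep("a", 8)), "2 or 3")
})

test_that("well-separated clusters are classified perfectly", {
  set.seed(10)
  X <- rbind(matrix(rnorm(20 * 5), 20, 5), matrix(rnorm(20 * 5, 10), 20, 5))
  y <- rep(c("a", "b"), each = 20)
  rep <- svm_classify(X, y, seed = 1)
  expect_equal(rep$balanced_accuracy, 1)
  expect_equal(rep$auc, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
})

test_that("uninformative features stay near chance", {
  set.seed(11)
  X <- matrix(rnorm(200 * 10), 200, 10)
  y <- rep(c("a", "b"), 100)
  rep <- svm_classify(X, y, seed = 2)
  expect_gt(rep$balanced_accuracy, 0.35)
  expect_lt(rep$balanced_accuracy, 0.65)
})

test_that("balanced accuracy is the mean of per-class recalls", {
  # fixed confusion: sensitivity 0.9, specificity 0.7 -> balanced 0.8
  truth <- factor(rep(c("pos", "neg"), c(10, 10)), levels = c("pos", "neg"))
  pred <- factor(c(rep("pos", 9), "neg", rep("neg", 7), rep("pos", 3)),
                 levels = c("pos", "neg"))
  mets <- molpert:::fold_metrics(pred, truth)
  expect_equal(unname(mets["balanced_accuracy"]), 0.8)
  expect_equal(unname(mets["sensitivity"]), 0.9)
  expect_equal(unname(mets["specificity"]), 0.7)
})

test_that("classification is deterministic given a seed and guards its inputs", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rep(c("a", "b"), 20)
  r1 <- svm_classify(X, y, seed = 5)
  r2 <- svm_classify(X, y, seed = 5)
  expect_identical(r1$balanced_accuracy, r2$balanced_accuracy)
  expect_identical(r1$per_fold, r2$per_fold)
  expect_error(svm_classify(X[1:7, ], y[1:7], seed = 1), "at least 4")
  expect_error(svm_classify(X, y, folds = 25, seed = 1), "fewer folds")
})

test_that("metrics are invariant to a common affine feature rescaling", {
  set.seed(13)
  X <- rbind(matrix(rnorm(15 * 4), 15, 4), matrix(rnorm(15 * 4, 2), 15, 4))
  y <- rep(c("a", "b"), each = 15)
  r1 <- svm_classify(X, y, seed = 3)
  r2 <- svm_classify(X * 50 + 100, y, seed = 3)
  expect_equal(r1$balanced_accuracy, r2$balanced_accuracy, tolerance = 1e-8)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-8)
})

test_that("three-class one-vs-one classification recovers separated groups", {
  set.seed(14)
  X <- rbind(matrix(rnorm(12 * 4, 0), 12, 4),
             matrix(rnorm(12 * 4, 6), 12, 4),
             matrix(rnorm(12 * 4, 12), 12, 4))
  y <- rep(c("a", "b", "c"), each = 12)
  rep <- svm_classify(X, y, seed = 4)
  expect_gt(rep$balanced_accuracy, 0.9)
  expect_gt(rep$auc, 0.95)
})

test_that("the permutation p follows the add-one rule and is seed-stable", {
  set.seed(15)
  X <- rbind(matrix(rnorm(20 * 3), 20, 3), matrix(rnorm(20 * 3, 8), 20, 3))
  y <- rep(c("a", "b"), each = 20)
  rep <- svm_permutation_test(X, y, n_perm = 99, seed = 6)
  # perfectly separable: no permutation can beat it, p = 1/(1+99)
  expect_equal(rep$permutation_p, 1 / 100)
  rep2 <- svm_permutation_test(X, y, n_perm = 99, seed = 6)
  expect_identical(rep$permutation_p, rep2$permutation_p)
  expect_identical(rep$null_accuracies, rep2$null_accuracies)
})

test_that("uninformative labels give a non-significant permutation p", {
  set.seed(16)
  X <- matrix(rnorm(60 * 5), 60, 5)
  y <- rep(c("a", "b"), 30)
  rep <- svm_permutation_test(X, y, n_perm = 99, seed = 7)
  expect_gt(rep$permutation_p, 0.05)
})

test_that("SMOTE balances classes by convex interpolation", {
  set.seed(17)
  X <- rbind(matrix(rnorm(6 * 3), 6, 3), matrix(rnorm(12 * 3, 4), 12, 3))
  y <- rep(c("min", "maj"), c(6, 12))
  bal <- smote_balance(X, y, k = 5, seed = 8)
  expect_equal(as.integer(table(bal$y)), c(12L, 12L))
  # each synthetic point lies on a segment between its parent and a true
  # k-neighbour: distance(parent, synth) + distance(synth, nb) ==
  # distance(parent, nb) for some minority pair
  synth <- bal$X[(nrow(X) + 1):nrow(bal$X), , drop = FALSE]
  Xmin <- X[y == "min", , drop = FALSE]
  for (s in seq_len(nrow(synth))) {
    on_segment <- FALSE
    for (i in seq_len(nrow(Xmin))) for (j in seq_len(nrow(Xmin))) {
      if (i == j) next
      dij <- sqrt(sum((Xmin[i, ] - Xmin[j, ])^2))
      dis <- sqrt(sum((Xmin[i, ] - synth[s, ])^2))
      dsj <- sqrt(sum((synth[s, ] - Xmin[j, ])^2))
      if (abs(dis + dsj - dij) < 1e-8) on_segment <- TRUE
    }
    expect_true(on_segment)
  }
  # balanced input unchanged
  yb <- rep(c("a", "b"), each = 6)
  bal2 <- smote_balance(X[1:12, ], yb, seed = 9)
  expect_identical(bal2$X, X[1:12, ])
  expect_error(smote_balance(X, y, k = 6), "smaller k")
})

test_that("SMOTE inside CV handles imbalanced groups", {
  set.seed(18)
  X <- rbind(matrix(rnorm(12 * 4), 12, 4), matrix(rnorm(30 * 4, 5), 30, 4))
  y <- rep(c("rare", "common"), c(12, 30))
  rep <- svm_classify(X, y, smote = TRUE, seed = 10)
  expect_gt(rep$balanced_accuracy, 0.9)
})

test_that("roc coordinates start at the origin and end at (1,1)", {
  rc <- roc_coordinates(c(3, 2, 1, 0), factor(c("a", "a", "b", "b")))
  expect_equal(rc$fpr[1], 0)
  expect_equal(rc$tpr[1], 0)
  expect_equal(rc$fpr[nrow(rc)], 1)
  expect_equal(rc$tpr[nrow(rc)], 1)
  expect_true(all(diff(rc$tpr) >= 0) && all(diff(rc$fpr) >= 0))
})
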