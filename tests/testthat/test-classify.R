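make_blob_table <- function(n_per = 20, sep = 6, seed = 42, p = 20) {
  # four well-separated Gaussian blobs in p dimensions
  centers <- diag(sep, 4, p)
  set.seed(seed)
  x <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(n_per * p), n_per, p), 2, centers[k, ], "+")))
  list(x = x, y = factor(rep(c(0, 30, 60, 120), each = n_per),
                         levels = c(0, 30, 60, 120)))
}

test_that("summary statistics reproduce the published classification table", {
  st <- confusion_stats(table1_svm)
  expect_equal(st$mean_accuracy, 86.3)          # (75+77+97+96)/4 rounded
  expect_equal(unname(st$pairwise_fnr["0", "30"]), 24)
  expect_equal(unname(st$tpr), c(75, 77, 97, 96))
  expect_equal(unname(st$fpr), c(25, 23, 3, 4))

  stp <- confusion_stats(table1_pca_svm)
  expect_equal(unname(stp$pairwise_fnr["0", "30"]), 29)
  expect_equal(unname(mean(stp$tpr[c("60", "120")])), 92.5)
  expect_equal(stp$mean_accuracy, 81.8)         # (70+72+92+93)/4 rounded
})

test_that("degenerate confusion matrices are handled explicitly", {
  ident <- diag(100, 4)
  st <- confusion_stats(ident)
  expect_equal(st$mean_accuracy, 100)
  expect_equal(unname(st$fpr), rep(0, 4))
  expect_error(confusion_stats(matrix(c(1, 0, 0, 0), 2, 2)), "empty")
  expect_error(confusion_matrix(matrix(1:6, 2, 3)), "square")
})

test_that("PCA projection captures planar data exactly and isotropic noise at 2/p", {
  set.seed(9)
  basis <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  planar <- matrix(rnorm(200), 100, 2) %*% t(basis)
  pr <- suppressWarnings(fit_pca(planar))
  expect_equal(pr$variance_fraction, 1, tolerance = 1e-9)
  expect_equal(crossprod(pr$rotation), diag(2), tolerance = 1e-9,
               ignore_attr = TRUE)

  iso <- matrix(rnorm(2000 * 20), 2000, 20)
  pr2 <- suppressWarnings(fit_pca(iso))
  expect_lt(abs(pr2$variance_fraction - 2 / 20), 0.05)
  expect_error(fit_pca(matrix(5, 10, 3)), "constant")
})

test_that("linear SVM separates separable clouds and rejects single-class input", {
  set.seed(10)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 8), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  fit <- train_linear_svm(x, y)
  expect_equal(mean(predict(fit, x) == y), 1)
  expect_error(train_linear_svm(x, rep("a", 100)), "2 classes")
})

test_that("duplicating every row leaves the decision function unchanged", {
  set.seed(12)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 3), 30, 2))
  y <- rep(c("a", "b"), each = 30)
  f1 <- train_linear_svm(x, y)
  f2 <- train_linear_svm(rbind(x, x), c(y, y))
  grid <- matrix(rnorm(40, 1.5), 20, 2)
  expect_equal(predict(f1, grid), predict(f2, grid), ignore_attr = TRUE)
})

test_that("cross-validation is stratified, deterministic, and leak-free", {
  blob <- make_blob_table()
  cm1 <- cross_validate(blob$x, blob$y, k_folds = 5, seed = 3)
  cm2 <- cross_validate(blob$x, blob$y, k_folds = 5, seed = 3)
  expect_identical(cm1$counts, cm2$counts)
  expect_equal(cm1$mean_accuracy, 100)          # fully separable blobs
  expect_equal(unname(rowSums(cm1$counts)), rep(20, 4))

  # a correlated sentinel block equal to the label dominates both pipelines:
  # fold-wise refitting must not dilute it for the PCA route
  lab <- as.numeric(as.character(blob$y))
  set.seed(99)
  sentinel <- cbind(matrix(rnorm(nrow(blob$x) * 5), ncol = 5),
                    lab, lab, lab)
  acc_raw <- cross_validate(sentinel, blob$y, k_folds = 5, seed = 3)
  acc_pca <- cross_validate(sentinel, blob$y, use_pca = TRUE, k_folds = 5,
                            seed = 3)
  expect_equal(acc_raw$mean_accuracy, 100)
  expect_gte(acc_pca$mean_accuracy, 95)

  few <- c(1:3, 21:23, 41:43, 61:63)      # 3 rows per class, 5 folds
  expect_error(cross_validate(blob$x[few, ], blob$y[few], k_folds = 5),
               "fewer than")
})

test_that("label permutation drives accuracy to chance", {
  blob <- make_blob_table(n_per = 15)
  acc <- permutation_null(blob$x, blob$y, n_perm = 10, k_folds = 3, seed = 5)
  expect_lt(abs(mean(acc) - 25), 8)
})

test_that("the texture_svm model object carries methods and predicts sensibly", {
  blob <- make_blob_table(n_per = 10)
  df <- data.frame(time_point = blob$y, blob$x)
  fit <- texture_svm(time_point ~ ., data = df, k_folds = 5, seed = 1)
  expect_s3_class(fit, "texture_svm")
  expect_equal(fit$confusion$mean_accuracy, 100)
  expect_output(print(fit), "mean accuracy")
  s <- summary(fit)
  expect_output(print(s), "TPR")
  pred <- predict(fit, df)
  expect_equal(mean(pred == blob$y), 1)

  # classes laid out in a 2-D subspace of the 20-D space: the PCA route
  # must recover them through its fold-wise projections
  set.seed(77)
  centers2 <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  basis <- qr.Q(qr(matrix(rnorm(40), 20, 2)))
  x2 <- do.call(rbind, lapply(1:4, function(k)
    (matrix(rnorm(20), 10, 2) + rep(centers2[k, ], each = 10)) %*% t(basis)))
  df2 <- data.frame(time_point = blob$y, x2)
  fitp <- texture_svm(time_point ~ ., data = df2, pca = TRUE, seed = 1)
  expect_false(is.null(fitp$pca))
  expect_gte(fitp$confusion$mean_accuracy, 95)
})
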