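#' Standardize, then project onto the top principal components
#'
#' Features are z-scored (zero-variance features get unit scale and a zero
#' score) and the leading eigenvectors of their covariance are retained.
#'
#' @param x numeric matrix, one row per observation.
#' @param n_components number of components kept (default 2).
#' @param warn_low_variance warn when the kept components capture less than
#'   95\% of the total variance (default TRUE).
#' @return object of class \code{"pca_projection"}: \code{rotation}
#'   (p x n_components, orthonormal columns), \code{center}, \code{scale},
#'   \code{sdev}, \code{variance_fraction}.
#' @export
fit_pca <- function(x, n_components = 2L, warn_low_variance = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("need at least 3 rows for PCA")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  if (all(scl == 0)) stop("all features are constant")
  if (sum(scl > 0) < 2L) stop("need at least 2 non-constant features")
  scl[scl == 0] <- 1
  z <- scale(x, center = ctr, scale = scl)
  pr <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pr$rotation))
  vf <- sum(pr$sdev[seq_len(n_components)]^2) / sum(pr$sdev^2)
  if (warn_low_variance && vf < 0.95)
    warning(sprintf("top %d components capture %.1f%% of the variance (< 95%%)",
                    n_components, 100 * vf))
  structure(list(rotation = pr$rotation[, seq_len(n_components), drop = FALSE],
                 center = ctr, scale = scl,
                 sdev = pr$sdev, variance_fraction = vf),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("PCA projection: %d features -> %d components, %.1f%% variance\n",
              nrow(x$rotation), ncol(x$rotation), 100 * x$variance_fraction))
  invisible(x)
}

#' @export
predict.pca_projection <- function(object, newdata, ...) {
  z <- scale(as.matrix(newdata), center = object$center, scale = object$scale)
  z %*% object$rotation
}

#' Linear-kernel support vector machine over a feature matrix
#'
#' Thin wrapper around \code{e1071::svm} pinning the study configuration:
#' linear kernel, C-classification, one-vs-one multiclass with voting,
#' no internal rescaling (features are standardized by the caller).
#' Deterministic given the data and C.
#'
#' @param x numeric feature matrix (standardized).
#' @param y class labels (factor or coercible).
#' @param C regularization constant (default 1).
#' @return fitted \code{svm} object.
#' @export
train_linear_svm <- function(x, y, C = 1) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("need at least 2 classes to train an SVM")
  e1071::svm(as.matrix(x), droplevels(y), kernel = "linear", cost = C,
             scale = FALSE, type = "C-classification")
}

# Stratified fold ids: within each class, shuffled labels cycle 1..k.
stratified_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      if (length(idx) < k)
        stop("class '", lv, "' has ", length(idx), " rows, fewer than ",
             k, " folds")
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Cross-validated confusion matrix of the texture classifier
#'
#' Stratified k-fold cross-validation of the standardize (+ optional PCA) +
#' linear-SVM chain. All preprocessing (z-scoring and, when enabled, the PCA
#' projection) is re-fit inside each training fold only, so no test-fold
#' information leaks into the features. Out-of-fold predictions are pooled
#' into one confusion matrix.
#'
#' @param features numeric matrix or data.frame of features, one row per VOI.
#' @param labels class label per row (e.g. time point in minutes).
#' @param use_pca project onto the first \code{n_components} principal
#'   components before the SVM (default FALSE).
#' @param k_folds number of folds (default 5).
#' @param C SVM regularization constant (default 1).
#' @param seed fold-assignment seed; the same seed reproduces the counts
#'   exactly.
#' @param n_components PCA dimensionality when \code{use_pca} (default 2).
#' @return object of class \code{"confusion_matrix"}; see
#'   \code{\link{confusion_matrix}}.
#' @export
cross_validate <- function(features, labels, use_pca = FALSE, k_folds = 5L,
                           C = 1, seed = 1L, n_components = 2L) {
  x <- as.matrix(features)
  if (anyNA(x)) stop("features contain missing values")
  y <- factor(labels)
  fold <- stratified_folds(y, k_folds, seed)
  lev <- levels(y)
  counts <- matrix(0L, nrow = length(lev), ncol = length(lev),
                   dimnames = list(true = lev, predicted = lev))
  vf <- numeric(0)
  for (f in seq_len(k_folds)) {
    tr <- fold != f; te <- !tr
    ctr <- colMeans(x[tr, , drop = FALSE])
    scl <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
    ztr <- scale(x[tr, , drop = FALSE], ctr, scl)
    zte <- scale(x[te, , drop = FALSE], ctr, scl)
    if (use_pca) {
      proj <- fit_pca(x[tr, , drop = FALSE], n_components,
                      warn_low_variance = FALSE)
      vf <- c(vf, proj$variance_fraction)
      ztr <- predict(proj, x[tr, , drop = FALSE])
      zte <- predict(proj, x[te, , drop = FALSE])
    }
    fit <- train_linear_svm(ztr, y[tr], C = C)
    pred <- predict(fit, zte)
    tab <- table(factor(y[te], levels = lev), factor(pred, levels = lev))
    counts <- counts + unclass(tab)
  }
  confusion_matrix(counts,
                   meta = list(use_pca = use_pca, k_folds = k_folds, C = C,
                               seed = seed,
                               pca_variance_fraction =
                                 if (use_pca) mean(vf) else NA_real_))
}

#' Confusion matrix with per-class rates
#'
#' Wraps 4-class (or any k-class) confusion counts with the derived
#' row-normalized percentages, per-class TPR (the diagonal percentage of the
#' row) and FPR reported, as in the study's summary-table convention, as the
#' row's off-diagonal percentage (100 - TPR), and the unweighted mean
#' accuracy across classes.
#'
#' @param counts square integer matrix, rows = true class, columns =
#'   predicted class.
#' @param meta optional list of provenance (CV settings, seed).
#' @return object of class \code{"confusion_matrix"}: list with
#'   \code{counts}, \code{percent}, \code{tpr}, \code{fpr},
#'   \code{mean_accuracy}, \code{meta}.
#' @export
confusion_matrix <- function(counts, meta = list()) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be square")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("empty true-class row in confusion matrix")
  percent <- sweep(counts, 1L, rs, "/") * 100
  tpr <- diag(percent)
  structure(list(counts = counts, percent = percent, tpr = tpr,
                 fpr = 100 - tpr,
                 mean_accuracy = mean(diag(percent)), meta = meta),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 1, ...) {
  cat("Cross-class confusion (row-normalized %):\n")
  print(round(x$percent, digits))
  cat(sprintf("mean accuracy: %.1f%%\n", x$mean_accuracy))
  invisible(x)
}

# round half away from zero to 'digits' decimals
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summary statistics of a confusion matrix
#'
#' Derives the study's reported quantities: per-class TPR/FPR, the unweighted
#' mean accuracy (mean of the diagonal row-percentages), and the pairwise
#' false-negative rate between every pair of classes, defined as the mean of
#' the two cross-cell percentages (a predicted as b, b predicted as a).
#' Percentages are rounded half away from zero to 1 decimal.
#'
#' @param cm a \code{"confusion_matrix"}, a matrix of counts, or a matrix of
#'   row-percentages (rows summing to 100).
#' @return list with \code{tpr}, \code{fpr}, \code{mean_accuracy},
#'   \code{pairwise_fnr} (symmetric matrix), and \code{percent}.
#' @export
confusion_stats <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) {
    m <- as.matrix(cm)
    if (nrow(m) != ncol(m)) stop("confusion matrix must be square")
    rs <- rowSums(m)
    if (any(rs == 0)) stop("empty true-class row in confusion matrix")
    if (all(abs(rs - 100) < 1e-6)) {
      percent <- m
    } else {
      percent <- sweep(m, 1L, rs, "/") * 100
    }
  } else {
    percent <- cm$percent
  }
  k <- nrow(percent)
  lev <- rownames(percent)
  if (is.null(lev)) lev <- as.character(seq_len(k))
  tpr <- round_half_up(diag(percent), 1L)
  pw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b)
    pw[a, b] <- round_half_up((percent[a, b] + percent[b, a]) / 2, 1L)
  list(tpr = tpr, fpr = round_half_up(100 - diag(percent), 1L),
       mean_accuracy = round_half_up(mean(diag(percent)), 1L),
       pairwise_fnr = pw,
       percent = percent)
}

#' Cross-validated accuracy of one class pair
#'
#' Restricts the table to two classes and returns the mean of the two
#' diagonal percentages of the pairwise cross-validated confusion matrix.
#'
#' @inheritParams cross_validate
#' @param pair length-2 vector of class labels.
#' @return single numeric percentage.
#' @export
pairwise_cv_accuracy <- function(features, labels, pair, use_pca = FALSE,
                                 k_folds = 5L, C = 1, seed = 1L) {
  keep <- labels %in% pair
  cm <- cross_validate(as.matrix(features)[keep, , drop = FALSE],
                       droplevels(factor(labels[keep])),
                       use_pca = use_pca, k_folds = k_folds, C = C,
                       seed = seed)
  cm$mean_accuracy
}

#' Permutation null of the cross-validated accuracy
#'
#' Re-runs cross-validation with the class labels randomly permuted; over
#' repeated permutations the mean accuracy should sit near chance (100/k %).
#'
#' @inheritParams cross_validate
#' @param n_perm number of permutations (default 20).
#' @return numeric vector of mean accuracies, one per permutation.
#' @export
permutation_null <- function(features, labels, n_perm = 20L, use_pca = FALSE,
                             k_folds = 5L, C = 1, seed = 1L) {
  perms <- with_seed(seed, replicate(n_perm, sample(length(labels)),
                                     simplify = FALSE))
  vapply(seq_len(n_perm), function(i) {
    cm <- cross_validate(features, labels[perms[[i]]], use_pca = use_pca,
                         k_folds = k_folds, C = C, seed = seed + i)
    cm$mean_accuracy
  }, numeric(1L))
}
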