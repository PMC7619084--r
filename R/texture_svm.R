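#' Fit the texture time-point classifier
#'
#' The package's central model: a linear-kernel support vector machine over
#' GLCM texture features (optionally projected onto the first two principal
#' components), with a stratified cross-validated confusion matrix computed
#' alongside the final fit. The formula names the label column on the left
#' and the feature columns on the right, e.g.
#' \code{time_point ~ .} over a feature table from
#' \code{\link{phantom_study}}.
#'
#' @param formula model formula; the response is the class label, the
#'   right-hand side selects numeric feature columns.
#' @param data data.frame holding the label and feature columns.
#' @param pca project onto the first \code{n_components} principal
#'   components before the SVM (default FALSE).
#' @param k_folds cross-validation folds (default 5).
#' @param C SVM regularization constant (default 1).
#' @param seed fold seed (default 1).
#' @param n_components PCA dimensionality (default 2).
#' @return object of class \code{"texture_svm"}: the final model (fit on all
#'   rows), its preprocessing parameters, the cross-validated
#'   \code{\link{confusion_matrix}}, and a PCA of the full table used for
#'   plotting.
#' @seealso \code{\link{cross_validate}}, \code{\link{confusion_stats}}
#' @export
texture_svm <- function(formula, data, pca = FALSE, k_folds = 5L, C = 1,
                        seed = 1L, n_components = 2L) {
  mf <- stats::model.frame(formula, data)
  y <- factor(stats::model.response(mf))
  x <- as.matrix(mf[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("all feature columns must be numeric")
  if (anyNA(x)) stop("features contain missing values")

  cm <- cross_validate(x, y, use_pca = pca, k_folds = k_folds, C = C,
                       seed = seed, n_components = n_components)
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[scl == 0] <- 1
  display_pca <- fit_pca(x, n_components = 2L, warn_low_variance = FALSE)
  proj <- if (pca) fit_pca(x, n_components, warn_low_variance = FALSE)
          else NULL
  z <- if (pca) predict(proj, x) else scale(x, ctr, scl)
  fit <- train_linear_svm(z, y, C = C)

  structure(list(call = match.call(), levels = levels(y),
                 feature_names = colnames(x),
                 center = ctr, scale = scl, pca = proj,
                 display_pca = display_pca, svm = fit, confusion = cm,
                 n = nrow(x), settings = list(pca = pca, k_folds = k_folds,
                                              C = C, seed = seed)),
            class = "texture_svm")
}

#' @export
print.texture_svm <- function(x, ...) {
  cat("Texture time-point classifier (linear SVM ",
      if (x$settings$pca) "on principal components" else "on raw features",
      ")\n", sep = "")
  cat(sprintf("  classes: %s; n = %d VOIs\n",
              paste(x$levels, collapse = ", "), x$n))
  cat(sprintf("  %d-fold cross-validated mean accuracy: %.1f%%\n",
              x$settings$k_folds, x$confusion$mean_accuracy))
  invisible(x)
}

#' @export
summary.texture_svm <- function(object, ...) {
  st <- confusion_stats(object$confusion)
  out <- list(model = object, stats = st)
  class(out) <- "summary.texture_svm"
  out
}

#' @export
print.summary.texture_svm <- function(x, ...) {
  print(x$model)
  cat("\nPredicted class (% correct), rows = true class:\n")
  tab <- cbind(round(x$stats$percent, 1), TPR = x$stats$tpr,
               FPR = x$stats$fpr)
  print(tab)
  cat(sprintf("\nmean accuracy: %.1f%%\n", x$stats$mean_accuracy))
  if (!is.null(x$model$pca))
    cat(sprintf("PCA variance captured by %d components: %.1f%%\n",
                ncol(x$model$pca$rotation),
                100 * x$model$pca$variance_fraction))
  invisible(x)
}

#' @export
predict.texture_svm <- function(object, newdata, ...) {
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  z <- if (!is.null(object$pca)) predict(object$pca, x)
       else scale(x, object$center, object$scale)
  predict(object$svm, z)
}

#' @export
plot.texture_svm <- function(x, data, labels = NULL, ...) {
  if (missing(data)) stop("supply the feature table used for fitting")
  feats <- as.matrix(data[, x$feature_names, drop = FALSE])
  if (is.null(labels)) labels <- data$time_point
  pcs <- predict(x$display_pca, feats)
  cls <- factor(labels)
  plot(pcs[, 1L], pcs[, 2L], col = as.integer(cls), pch = as.integer(cls),
       xlab = sprintf("PC1 (%.0f%% var)", 100 * x$display_pca$sdev[1L]^2 /
                        sum(x$display_pca$sdev^2)),
       ylab = sprintf("PC2 (%.0f%% var)", 100 * x$display_pca$sdev[2L]^2 /
                        sum(x$display_pca$sdev^2)), ...)
  legend("topright", legend = levels(cls), col = seq_len(nlevels(cls)),
         pch = seq_len(nlevels(cls)), title = "time (min)", bty = "n")
  invisible(pcs)
}

#' Full phantom study: volumes, VOIs and the texture feature table
#'
#' Emulates the study design on the synthetic phantom: for each time point
#' (default 0, 30, 60, 120 min) and each of \code{n_retinas} retinas,
#' \code{images_per_retina} volumes are generated and
#' \code{vois_per_image} VOIs are sampled from each IPL, giving
#' 4 x 3 x 2 x 10 = 240 VOIs by default. Each VOI contributes one
#' 20-dimensional GLCM feature vector.
#'
#' @param seed master seed; every volume and VOI draw derives its own
#'   sub-seed from it.
#' @param time_points acquisition times in minutes.
#' @param n_retinas,images_per_retina,vois_per_image study design counts.
#' @param voi_size VOI edge length in voxels (default 30).
#' @param levels,distance GLCM quantization levels and offset.
#' @param params_fn function(t, seed) returning
#'   \code{\link{phantom_params}}; replace to change phantom defaults.
#' @return data.frame with columns \code{time_point}, \code{retina},
#'   \code{source_image_id}, the VOI origin columns \code{x}, \code{z},
#'   \code{y}, and the 20 feature columns.
#' @export
phantom_study <- function(seed = 1L,
                          time_points = c(0, 30, 60, 120),
                          n_retinas = 3L, images_per_retina = 2L,
                          vois_per_image = 10L, voi_size = 30L,
                          levels = 64L, distance = 1L,
                          params_fn = function(t, seed)
                            phantom_params(t = t, seed = seed,
                                           voi_size = voi_size)) {
  rows <- list()
  img_counter <- 0L
  for (t in time_points) {
    for (r in seq_len(n_retinas)) {
      for (im in seq_len(images_per_retina)) {
        img_counter <- img_counter + 1L
        sub_seed <- (seed * 10007L + img_counter * 131L) %% 2147483647L
        vol <- generate_volume(params_fn(t, sub_seed))
        id <- sprintf("t%03d_r%d_i%d", t, r, im)
        vois <- sample_vois(vol$stack, vol$ipl_mask, vois_per_image,
                            seed = sub_seed + 1L, size = voi_size,
                            source_image_id = id, time_point = t)
        feats <- t(vapply(seq_len(nrow(vois)), function(k) {
          voi_feature_vector(extract_voi(vol$stack, vois[k, ]),
                             levels = levels, distance = distance)
        }, numeric(20L)))
        colnames(feats) <- .glcm_feature_names()
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(time_point = t, retina = r,
                           source_image_id = id,
                           x = vois$x, z = vois$z, y = vois$y,
                           stringsAsFactors = FALSE),
                as.data.frame(feats))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Names of the 20 GLCM feature columns
#' @return character vector of length 20.
#' @export
glcm_feature_names <- function() .glcm_feature_names()
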