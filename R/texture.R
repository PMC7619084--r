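#' Quantize 8-bit intensities to G grey levels
#'
#' Uniform binning of the full 8-bit range \code{[0, 255]} into \code{levels}
#' bins with fixed bin edges (bin width \code{256/levels}), independent of the
#' data actually present. Fixed edges make features comparable across VOIs and
#' keep contrast/homogeneity invariant when all intensities shift by a whole
#' number of bin widths.
#'
#' @param x numeric vector, matrix or array of intensities in \code{[0, 255]}.
#' @param levels number of grey levels G (default 64).
#' @return integer object of the same shape with values in \code{0..levels-1}.
#' @export
quantize_levels <- function(x, levels = 64L) {
  levels <- as.integer(levels)
  if (levels < 2L) stop("'levels' must be at least 2")
  if (any(!is.finite(x))) stop("intensities must be finite")
  if (any(x < 0 | x > 255)) stop("intensities must lie in [0, 255]")
  q <- pmin(as.integer(floor(x * (levels / 256))), levels - 1L)
  dim(q) <- dim(x)
  q
}

.glcm_offsets <- list(
  `0`   = c(0L,  1L),   # reference -> index one pixel to the right
  `90`  = c(-1L, 0L),   # one pixel up
  `180` = c(0L, -1L),   # one pixel left
  `270` = c(1L,  0L)    # one pixel down
)

#' Grey-level co-occurrence matrix of a 2D slice
#'
#' Counts ordered pixel pairs (reference value i, offset value j) at a fixed
#' displacement and normalizes to joint probabilities. Matrices are NOT
#' symmetrized: opposite directions give transposed matrices, which keeps the
#' four directions distinct as separate feature channels.
#'
#' @param slice 2D matrix of intensities in \code{[0, 255]} (or already
#'   quantized codes when \code{quantized = TRUE}).
#' @param direction one of 0, 90, 180, 270 (degrees). 0 deg pairs each pixel
#'   with the pixel \code{distance} columns to its right; 90 deg with the pixel
#'   \code{distance} rows above; 180/270 the opposites.
#' @param distance pixel offset d (default 1).
#' @param levels number of grey levels G used for quantization (default 64).
#' @param quantized set TRUE when \code{slice} already holds codes in
#'   \code{0..levels-1}.
#' @return object of class \code{"glcm"}: list with \code{p} (G x G probability
#'   matrix, rows = reference level i, cols = index level j), \code{direction},
#'   \code{distance}, \code{levels}, \code{n_pairs}.
#' @export
compute_glcm <- function(slice, direction = 0, distance = 1L, levels = 64L,
                         quantized = FALSE) {
  if (!is.matrix(slice)) stop("'slice' must be a 2D matrix")
  direction <- as.character(direction)
  if (!direction %in% names(.glcm_offsets))
    stop("'direction' must be one of 0, 90, 180, 270 degrees")
  distance <- as.integer(distance)
  if (distance < 1L) stop("'distance' must be >= 1")
  levels <- as.integer(levels)
  q <- if (quantized) {
    storage.mode(slice) <- "integer"
    if (any(slice < 0L | slice >= levels)) stop("quantized codes out of range")
    slice
  } else quantize_levels(slice, levels)

  off <- .glcm_offsets[[direction]] * distance
  nr <- nrow(q); nc <- ncol(q)
  r0 <- max(1L, 1L - off[1L]); r1 <- min(nr, nr - off[1L])
  c0 <- max(1L, 1L - off[2L]); c1 <- min(nc, nc - off[2L])
  if (r0 > r1 || c0 > c1)
    stop("slice too small: no pixel pair exists at distance ", distance,
         " in direction ", direction)
  ref <- q[r0:r1, c0:c1, drop = FALSE]
  idx <- q[(r0 + off[1L]):(r1 + off[1L]), (c0 + off[2L]):(c1 + off[2L]),
           drop = FALSE]
  counts <- tabulate(as.vector(ref) * levels + as.vector(idx) + 1L,
                     nbins = levels * levels)
  n_pairs <- sum(counts)
  p <- matrix(counts / n_pairs, nrow = levels, ncol = levels, byrow = TRUE)
  structure(list(p = p, direction = as.numeric(direction),
                 distance = distance, levels = levels, n_pairs = n_pairs),
            class = "glcm")
}

#' @export
print.glcm <- function(x, ...) {
  cat(sprintf("GLCM: %d grey levels, direction %g deg, distance %d, %d pairs\n",
              x$levels, x$direction, x$distance, x$n_pairs))
  invisible(x)
}

#' Haralick-style features of one GLCM
#'
#' energy = sum p^2; contrast = sum (i-j)^2 p; entropy = -sum p log p;
#' correlation = sum (i-mu_i)(j-mu_j) p / (sigma_i sigma_j);
#' homogeneity = sum p / (1 + (i-j)^2) (inverse difference moment), with
#' \code{1 + |i-j|} available as a variant. i, j are grey-level codes.
#'
#' Correlation is undefined when either marginal has zero variance (e.g. a
#' constant slice); it is returned as \code{NA} with attribute
#' \code{undefined_correlation = TRUE} rather than silently propagating NaN.
#'
#' @param g object of class \code{"glcm"}.
#' @param entropy_base base of the entropy logarithm: "ln" (natural, default),
#'   "log2" or "log10". A base change rescales entropy by a constant only.
#' @param homogeneity one of "squared" (1 + (i-j)^2, default) or "abs"
#'   (1 + |i-j|).
#' @return named numeric vector: energy, contrast, entropy, correlation,
#'   homogeneity.
#' @export
glcm_features <- function(g, entropy_base = c("ln", "log2", "log10"),
                          homogeneity = c("squared", "abs")) {
  stopifnot(inherits(g, "glcm"))
  entropy_base <- match.arg(entropy_base)
  homogeneity <- match.arg(homogeneity)
  p <- g$p
  G <- g$levels
  i <- matrix(0:(G - 1L), nrow = G, ncol = G)              # reference (row)
  j <- t(i)                                                # index (col)
  energy <- sum(p * p)
  d2 <- (i - j)^2
  contrast <- sum(d2 * p)
  pos <- p > 0
  logf <- switch(entropy_base, ln = log, log2 = log2, log10 = log10)
  entropy <- -sum(p[pos] * logf(p[pos]))
  hden <- if (homogeneity == "squared") 1 + d2 else 1 + abs(i - j)
  homog <- sum(p / hden)
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum((0:(G - 1L)) * pi_); mu_j <- sum((0:(G - 1L)) * pj)
  var_i <- sum(((0:(G - 1L)) - mu_i)^2 * pi_)
  var_j <- sum(((0:(G - 1L)) - mu_j)^2 * pj)
  if (var_i <= 0 || var_j <= 0) {
    correlation <- NA_real_
    out <- c(energy = energy, contrast = contrast, entropy = entropy,
             correlation = correlation, homogeneity = homog)
    attr(out, "undefined_correlation") <- TRUE
    return(out)
  }
  correlation <- sum((i - mu_i) * (j - mu_j) * p) / sqrt(var_i * var_j)
  c(energy = energy, contrast = contrast, entropy = entropy,
    correlation = correlation, homogeneity = homog)
}

.glcm_feature_names <- function() {
  as.vector(outer(c("energy", "contrast", "entropy", "correlation",
                    "homogeneity"),
                  c("0", "90", "180", "270"), paste, sep = "_"))
}

#' 20-dimensional texture feature vector of one VOI
#'
#' For each of the four directions (0, 90, 180, 270 deg) the five GLCM
#' features are computed on every en-face (x-z) slice of the block and
#' averaged across slices, giving 5 features x 4 directions = 20 values.
#' Slices whose correlation is undefined (zero grey-level variance) are
#' dropped from the correlation average with a warning; if every slice is
#' degenerate the correlation entries are NA.
#'
#' @param block 3D array of intensities, dimensions (y depth, x, z) as
#'   returned by \code{\link{extract_voi}}.
#' @param levels grey levels G for quantization (default 64).
#' @param distance GLCM pixel offset (default 1).
#' @param entropy_base,homogeneity passed to \code{\link{glcm_features}}.
#' @return named numeric vector of length 20, names
#'   \code{<feature>_<direction>} in the order energy, contrast, entropy,
#'   correlation, homogeneity for 0, then 90, 180, 270 deg.
#' @export
voi_feature_vector <- function(block, levels = 64L, distance = 1L,
                               entropy_base = "ln", homogeneity = "squared") {
  if (length(dim(block)) != 3L) stop("'block' must be a 3D array")
  dirs <- c(0, 90, 180, 270)
  ny <- dim(block)[1L]
  acc <- matrix(0, nrow = 5L, ncol = 4L,
                dimnames = list(c("energy", "contrast", "entropy",
                                  "correlation", "homogeneity"), dirs))
  n_corr <- rep(0L, 4L)
  n_skipped <- 0L
  for (iy in seq_len(ny)) {
    q <- quantize_levels(block[iy, , ], levels)
    for (k in seq_along(dirs)) {
      g <- compute_glcm(q, direction = dirs[k], distance = distance,
                        levels = levels, quantized = TRUE)
      f <- glcm_features(g, entropy_base = entropy_base,
                         homogeneity = homogeneity)
      acc[c(1L, 2L, 3L, 5L), k] <- acc[c(1L, 2L, 3L, 5L), k] +
        f[c("energy", "contrast", "entropy", "homogeneity")]
      if (is.na(f["correlation"])) {
        n_skipped <- n_skipped + 1L
      } else {
        acc["correlation", k] <- acc["correlation", k] + f["correlation"]
        n_corr[k] <- n_corr[k] + 1L
      }
    }
  }
  out <- acc
  out[c(1L, 2L, 3L, 5L), ] <- out[c(1L, 2L, 3L, 5L), ] / ny
  for (k in seq_along(dirs))
    out["correlation", k] <- if (n_corr[k] > 0L)
      out["correlation", k] / n_corr[k] else NA_real_
  if (n_skipped > 0L)
    warning(n_skipped, " slice/direction case(s) had undefined correlation ",
            "(zero grey-level variance) and were skipped for that feature")
  v <- as.vector(out)
  names(v) <- .glcm_feature_names()
  v
}
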