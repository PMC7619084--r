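#' Edge spread function of an axis-aligned edge micrograph
#'
#' Averages the intensity profile perpendicular to an (approximately)
#' axis-aligned edge over all parallel scan lines in the region of interest.
#' For a blurred step the result is the sigmoid-shaped ESF whose derivative is
#' the line spread function. No slant-edge sub-pixel registration is applied:
#' the edge is assumed parallel to an image axis.
#'
#' @param image 2D numeric matrix of intensities.
#' @param edge_axis axis along which intensity varies across the edge:
#'   \code{"col"} (default, vertical edge, profile taken along columns) or
#'   \code{"row"} (horizontal edge).
#' @param roi optional list with integer vectors \code{rows} and/or
#'   \code{cols} restricting the analysed region.
#' @param contrast_floor minimum intensity swing (max - min of the averaged
#'   profile) below which no edge is considered present (default 10 grey
#'   levels).
#' @return object of class \code{"intensity_profile"}: list with
#'   \code{values} (numeric vector) and \code{spacing} (pixels per sample, 1).
#' @export
edge_spread_function <- function(image, edge_axis = c("col", "row"),
                                 roi = NULL, contrast_floor = 10) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  edge_axis <- match.arg(edge_axis)
  if (!is.null(roi)) {
    if (!is.null(roi$rows)) image <- image[roi$rows, , drop = FALSE]
    if (!is.null(roi$cols)) image <- image[, roi$cols, drop = FALSE]
  }
  values <- if (edge_axis == "col") colMeans(image) else rowMeans(image)
  if (diff(range(values)) < contrast_floor)
    stop("no edge detected: intensity swing ",
         format(diff(range(values)), digits = 3), " is below the contrast ",
         "floor of ", contrast_floor)
  structure(list(values = as.numeric(values), spacing = 1),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity profile: %d samples, spacing %g px, range [%g, %g]\n",
              length(x$values), x$spacing, min(x$values), max(x$values)))
  invisible(x)
}

#' Line spread function as the derivative of an ESF
#'
#' Central differences in the interior, one-sided differences at the
#' endpoints; the result is normalized to unit area (sum x spacing = 1).
#' The central difference equals the true LSF locally averaged over a
#' two-sample window, whose frequency response sinc(2 nu) can be compensated
#' downstream (see \code{\link{mtf_curve}}).
#'
#' @param esf object of class \code{"intensity_profile"} (the ESF).
#' @return object of class \code{"intensity_profile"} holding the normalized
#'   LSF, with attribute \code{derivative_kernel = "central"}.
#' @export
line_spread_function <- function(esf) {
  stopifnot(inherits(esf, "intensity_profile"))
  v <- esf$values
  n <- length(v)
  if (n < 3L) stop("ESF must have at least 3 samples")
  d <- numeric(n)
  d[1L] <- v[2L] - v[1L]
  d[n] <- v[n] - v[n - 1L]
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / 2
  area <- sum(d) * esf$spacing
  if (abs(area) < .Machine$double.eps * n * max(1, max(abs(v))))
    stop("flat profile: ESF derivative has zero area")
  out <- structure(list(values = d / area, spacing = esf$spacing),
                   class = "intensity_profile")
  attr(out, "derivative_kernel") <- "central"
  out
}

#' Modulation transfer function curve from a line spread function
#'
#' Modulus of the discrete Fourier transform of the LSF, normalized by its
#' zero-frequency modulus and reported on [0, Nyquist] in cycles/pixel. The
#' LSF is zero-padded to \code{pad_factor} times its length so the curve is
#' sampled densely. When the LSF came from a finite-difference derivative of
#' an ESF, \code{correct_derivative = TRUE} divides out the known frequency
#' response of that difference kernel (sinc(2 nu) for central differences),
#' clamped away from its Nyquist zero, recovering the underlying optical MTF.
#'
#' @param lsf object of class \code{"intensity_profile"}.
#' @param pad_factor zero-padding factor (default 4).
#' @param correct_derivative divide by the difference-kernel response
#'   (default FALSE; only meaningful for an LSF from
#'   \code{\link{line_spread_function}}).
#' @param response_floor smallest kernel response divided out when
#'   correcting (default 0.1); below it the raw value is kept.
#' @return object of class \code{"mtf_curve"}: list with \code{frequencies}
#'   (cycles/pixel, 0 to Nyquist) and \code{values} (first value exactly 1).
#' @export
mtf_curve <- function(lsf, pad_factor = 4L, correct_derivative = FALSE,
                      response_floor = 0.1) {
  stopifnot(inherits(lsf, "intensity_profile"))
  v <- lsf$values
  if (!all(is.finite(v))) stop("LSF must be finite")
  if (all(v == 0)) stop("LSF is identically zero")
  pad_factor <- max(1L, as.integer(pad_factor))
  n <- length(v) * pad_factor
  mod <- Mod(stats::fft(c(v, rep(0, n - length(v)))))
  if (mod[1L] == 0) stop("zero DC component: LSF sums to zero")
  nu <- (seq_len(n) - 1L) / n / lsf$spacing
  keep <- nu <= 0.5 / lsf$spacing + 1e-12
  nu <- nu[keep]; mod <- mod[keep]
  if (correct_derivative) {
    resp <- abs(sinc_(2 * nu * lsf$spacing))
    adj <- resp >= response_floor
    mod[adj] <- mod[adj] / resp[adj]
  }
  structure(list(frequencies = nu, values = mod / mod[1L]),
            class = "mtf_curve")
}

sinc_ <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("MTF curve: %d frequencies in [0, %.4g] cycles/pixel\n",
              length(x$frequencies), max(x$frequencies)))
  f50 <- x$frequencies[which(x$values <= 0.5)[1L]]
  if (!is.na(f50)) cat(sprintf("  first frequency with MTF <= 0.5: %.4g\n", f50))
  invisible(x)
}

#' @export
plot.mtf_curve <- function(x, ...) {
  plot(x$frequencies, x$values, type = "l",
       xlab = "spatial frequency (cycles/pixel)",
       ylab = "normalized modulation factor", ylim = c(0, 1), ...)
  invisible(x)
}

#' Michelson modulation depth of an intensity pair
#'
#' m = (Imax - Imin) / (Imax + Imin), the contrast of a periodic target
#' read from the extreme intensities of its micrograph.
#'
#' @param i_max,i_min maximum and minimum image intensity (0-255).
#' @return object of class \code{"modulation_depth"}: list with \code{i_max},
#'   \code{i_min}, \code{m}.
#' @export
modulation_depth <- function(i_max, i_min) {
  if (!is.finite(i_max) || !is.finite(i_min)) stop("intensities must be finite")
  if (i_min > i_max) stop("'i_min' must not exceed 'i_max'")
  if (i_min < 0) stop("intensities must be non-negative")
  if (i_max + i_min == 0) stop("both intensities are zero: depth undefined")
  structure(list(i_max = i_max, i_min = i_min,
                 m = (i_max - i_min) / (i_max + i_min)),
            class = "modulation_depth")
}

#' @export
print.modulation_depth <- function(x, ...) {
  cat(sprintf("modulation depth m = %.4f (Imax = %g, Imin = %g)\n",
              x$m, x$i_max, x$i_min))
  invisible(x)
}

#' Contrast-transfer ratio of two modulation depths
#'
#' MTF(fx) = M_I(fx) / M_O(fx): the modulation depth of the grid-line image
#' seen through the tissue divided by that of the bare calibration slide.
#' 1 means perfectly transparent tissue, 0 fully opacified.
#'
#' @param m_image \code{"modulation_depth"} of the image with the specimen.
#' @param m_object \code{"modulation_depth"} of the control image without it.
#' @return single numeric ratio.
#' @export
mtf_ratio <- function(m_image, m_object) {
  stopifnot(inherits(m_image, "modulation_depth"),
            inherits(m_object, "modulation_depth"))
  if (m_object$m <= 0) stop("object modulation depth is zero: ratio undefined")
  m_image$m / m_object$m
}

#' Modulation depth measured from a graticule micrograph
#'
#' Takes Imax/Imin as robust extrema of the pixel intensities (percentiles,
#' by default the 5th and 95th) so noise tails do not drive the
#' contrast estimate; set \code{percentiles = c(0, 1)} for raw min/max.
#'
#' @param image 2D numeric matrix containing a periodic line pattern.
#' @param percentiles length-2 vector of lower/upper probability for the
#'   extrema (default \code{c(0.05, 0.95)}).
#' @return object of class \code{"modulation_depth"}. A flat image yields
#'   m = 0 with a warning.
#' @export
measure_graticule_modulation <- function(image, percentiles = c(0.05, 0.95)) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  stopifnot(length(percentiles) == 2L, percentiles[1L] < percentiles[2L])
  qs <- stats::quantile(image, probs = percentiles, names = FALSE, type = 7)
  if (qs[2L] <= qs[1L]) {
    warning("flat image: modulation depth is 0")
    qs <- rep(mean(image), 2L)
    if (qs[1L] == 0) qs <- c(1, 1)   # all-zero image: define m = 0 via equal pair
  }
  modulation_depth(qs[2L], qs[1L])
}

#' End-to-end MTF of an edge micrograph
#'
#' Convenience chain ESF -> LSF -> MTF curve with the finite-difference
#' response compensated, so a Gaussian-blurred edge of width sigma recovers
#' the analytic Gaussian MTF exp(-2 pi^2 sigma^2 nu^2).
#'
#' @inheritParams edge_spread_function
#' @inheritParams mtf_curve
#' @return object of class \code{"mtf_curve"}.
#' @export
edge_target_mtf <- function(image, edge_axis = "col", roi = NULL,
                            pad_factor = 4L) {
  esf <- edge_spread_function(image, edge_axis = edge_axis, roi = roi)
  lsf <- line_spread_function(esf)
  mtf_curve(lsf, pad_factor = pad_factor, correct_derivative = TRUE)
}
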