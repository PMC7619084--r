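#' 8-bit image stack container
#'
#' A 3D grid of 8-bit intensities with the OCT axis convention used
#' throughout the package: array dimensions are (y depth, x fast-scan,
#' z slow-scan), so \code{voxels[, , k]} is the k-th B-scan (depth x fast
#' axis) and \code{voxels[j, , ]} is an en-face plane at depth j.
#'
#' @param voxels 3D numeric/integer array with values in \code{[0, 255]}.
#' @param pixel_size optional physical scale in micrometres per voxel,
#'   length 1 or 3.
#' @return object of class \code{"image_stack"}.
#' @export
image_stack <- function(voxels, pixel_size = NULL) {
  if (length(dim(voxels)) != 3L) stop("'voxels' must be a 3D array")
  if (length(voxels) == 0L) stop("'voxels' must be non-empty")
  if (any(!is.finite(voxels))) stop("'voxels' must be finite")
  if (any(voxels < 0 | voxels > 255)) stop("intensities must lie in [0, 255]")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, pixel_size = pixel_size),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d (depth y) x %d (x) x %d (z), 8-bit\n",
              d[1L], d[2L], d[3L]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Read a multi-page 8-bit grayscale TIFF as an image stack
#'
#' Each page becomes one B-scan (depth x fast-scan matrix); the page index is
#' the slow-scan (z) axis. In strict mode (default) non-grayscale or
#' deeper-than-8-bit input is rejected; with \code{strict = FALSE} RGB pages
#' are converted by the luminosity weights 0.299/0.587/0.114 and deeper
#' samples are rescaled to 8-bit.
#'
#' @param path path to an existing TIFF file.
#' @param strict reject non-8-bit-grayscale input (default TRUE).
#' @return object of class \code{"image_stack"}.
#' @export
read_tiff_stack <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(pg) {
    if (length(dim(pg)) == 3L) {
      if (strict)
        stop("unsupported sample format: multi-channel TIFF in strict mode")
      pg <- 0.299 * pg[, , 1L] + 0.587 * pg[, , 2L] + 0.114 * pg[, , 3L]
    }
    if (max(pg) > 255) {
      if (strict)
        stop("unsupported sample format: more than 8 bits per sample in ",
             "strict mode")
      pg <- pg / max(pg) * 255
    }
    pg
  })
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(pg) identical(dim(pg), d), logical(1L))))
    stop("TIFF pages differ in size")
  vox <- array(0L, dim = c(d[1L], d[2L], length(pages)))
  for (k in seq_along(pages)) vox[, , k] <- round_half_away(pages[[k]])
  image_stack(vox)
}

#' Write an image stack as a multi-page 8-bit grayscale TIFF
#'
#' Round-trips bit-exactly with \code{\link{read_tiff_stack}}.
#'
#' @param stack object of class \code{"image_stack"} (or a 3D array in the
#'   same axis order).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  vox <- if (inherits(stack, "image_stack")) stack$voxels else stack
  if (length(dim(vox)) != 3L) stop("'stack' must be 3D")
  pages <- lapply(seq_len(dim(vox)[3L]),
                  function(k) vox[, , k, drop = TRUE] / 255)
  tiff::writeTIFF(pages, where = path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Round half away from zero (8-bit re-quantization convention)
#'
#' @param x numeric.
#' @param clip clip to \code{[0, 255]} before rounding (default TRUE).
#' @return integer object of the same shape.
#' @export
round_half_away <- function(x, clip = TRUE) {
  if (clip) x <- pmin(pmax(x, 0), 255)
  r <- as.integer(sign(x) * floor(abs(x) + 0.5))
  dim(r) <- dim(x)
  r
}

#' FFT notch filter for line-scan stripe artefacts
#'
#' Suppresses the spectral line on which artefact stripes concentrate: a
#' stripe running along image rows is constant along its row, so its energy
#' sits on the zero-column-frequency axis of the 2D Fourier plane (at every
#' row frequency). A Gaussian notch of width \code{notch_width} bins is
#' applied across that axis, excluding a protected low-frequency zone of
#' \code{dc_protect} bins around DC so the image mean and smooth background
#' pass unchanged. The filter is linear; re-quantization to 8-bit (clip to
#' [0, 255], round half away from zero) is applied last and can be disabled.
#'
#' @param image 2D numeric matrix.
#' @param notch_width Gaussian width of the notch in frequency bins
#'   (default 3); 0 disables filtering (identity up to re-quantization).
#' @param axis direction the artefact lines run along: \code{"row"}
#'   (horizontal stripes, default) or \code{"col"}.
#' @param dc_protect half-width in bins of the protected zone around DC
#'   along the notched axis (default 2).
#' @param quantize re-quantize the output to 8-bit (default TRUE).
#' @return filtered matrix (integer when \code{quantize = TRUE}).
#' @export
fft_line_filter <- function(image, notch_width = 3, axis = c("row", "col"),
                            dc_protect = 2L, quantize = TRUE) {
  if (!is.matrix(image)) stop("'image' must be a 2D matrix")
  axis <- match.arg(axis)
  if (notch_width < 0) stop("'notch_width' must be >= 0")
  nr <- nrow(image); nc <- ncol(image)
  nyq <- floor(min(nr, nc) / 2)
  if (notch_width > nyq)
    stop("'notch_width' (", notch_width, ") exceeds the Nyquist bin (", nyq,
         ")")
  if (notch_width == 0)
    return(if (quantize) round_half_away(image) else image)

  wrap <- function(n) { k <- 0:(n - 1L); ifelse(k > n / 2, k - n, k) }
  kr <- wrap(nr); kc <- wrap(nc)
  if (axis == "row") {
    # stripes along rows: notch small |kc|, protect small |kr|
    notch <- outer(abs(kr) > dc_protect,
                   exp(-kc^2 / (2 * notch_width^2)))
  } else {
    notch <- outer(exp(-kr^2 / (2 * notch_width^2)),
                   abs(kc) > dc_protect)
  }
  mask <- 1 - notch
  f <- stats::fft(image) * mask
  out <- Re(stats::fft(f, inverse = TRUE)) / (nr * nc)
  if (quantize) round_half_away(out) else out
}
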