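#' Randomly place cubic VOIs inside the IPL
#'
#' Reproduces the study's sampling scheme: the lateral (x, z) origin of each
#' 30x30x30-voxel volume of interest is drawn by a random number generator;
#' the depth (y) origin is anchored to the IPL/GCL border at that lateral
#' position and, when the IPL is thicker than the VOI, drawn uniformly so the
#' whole VOI lies between the border and the far edge of the IPL. VOIs may
#' overlap but identical origins are rejected; any voxel falling outside the
#' IPL mask, or inside the optional exclusion mask (e.g. blood vessels),
#' invalidates a candidate.
#'
#' Coordinates are 0-based with half-open extent [origin, origin + size).
#'
#' @param volume \code{\link{image_stack}} (or 3D array, axis order y, x, z).
#' @param ipl_mask logical array of the same dimensions, TRUE inside the IPL.
#' @param n_per_image number of VOIs to place.
#' @param seed integer RNG seed; fixed seed gives an identical VOI list.
#' @param exclusion_mask optional logical array, TRUE where placement is
#'   forbidden.
#' @param size VOI edge length in voxels (default 30).
#' @param max_attempts candidate draws before giving up (default
#'   \code{200 * n_per_image}).
#' @param source_image_id identifier copied into every VOI row.
#' @param time_point acquisition time in minutes copied into every VOI row.
#' @return data.frame of class \code{"voi_set"} with one row per VOI:
#'   columns \code{x}, \code{z}, \code{y} (0-based origins), \code{size},
#'   \code{source_image_id}, \code{time_point}.
#' @export
sample_vois <- function(volume, ipl_mask, n_per_image, seed = 1L,
                        exclusion_mask = NULL, size = 30L,
                        max_attempts = 200L * n_per_image,
                        source_image_id = "image", time_point = NA_real_) {
  vox <- if (inherits(volume, "image_stack")) volume$voxels else volume
  d <- dim(vox)
  if (!identical(dim(ipl_mask), d))
    stop("'ipl_mask' dimensions must match the volume")
  if (!is.null(exclusion_mask) && !identical(dim(exclusion_mask), d))
    stop("'exclusion_mask' dimensions must match the volume")
  size <- as.integer(size)
  if (size < 1L || size > min(d)) stop("'size' does not fit in the volume")

  got <- matrix(integer(0), ncol = 3L)   # 0-based (x, z, y)
  with_seed(seed, {
    attempts <- 0L
    while (nrow(got) < n_per_image && attempts < max_attempts) {
      attempts <- attempts + 1L
      x0 <- sample.int(d[2L] - size + 1L, 1L) - 1L
      z0 <- sample.int(d[3L] - size + 1L, 1L) - 1L
      # IPL/GCL border: first in-layer depth on the column at the VOI origin
      col_mask <- ipl_mask[, x0 + 1L, z0 + 1L]
      border <- which(col_mask)[1L]
      if (is.na(border)) next
      thick <- which(!col_mask[border:d[1L]])[1L] - 1L
      if (is.na(thick)) thick <- d[1L] - border + 1L
      if (thick < size) next
      y0 <- border - 1L + (sample.int(thick - size + 1L, 1L) - 1L)
      if (nrow(got) > 0L &&
          any(got[, 1L] == x0 & got[, 2L] == z0 & got[, 3L] == y0)) next
      ys <- (y0 + 1L):(y0 + size); xs <- (x0 + 1L):(x0 + size)
      zs <- (z0 + 1L):(z0 + size)
      if (!all(ipl_mask[ys, xs, zs])) next
      if (!is.null(exclusion_mask) && any(exclusion_mask[ys, xs, zs])) next
      got <- rbind(got, c(x0, z0, y0))
    }
  })
  if (nrow(got) < n_per_image)
    stop("could only place ", nrow(got), " of ", n_per_image,
         " VOIs within ", max_attempts, " attempts")
  out <- data.frame(x = got[, 1L], z = got[, 2L], y = got[, 3L],
                    size = size, source_image_id = source_image_id,
                    time_point = time_point, stringsAsFactors = FALSE)
  class(out) <- c("voi_set", class(out))
  out
}

#' Extract the intensity block of one VOI
#'
#' Returns a copy (never a view) of the \code{size^3} block addressed by a
#' VOI row, using the 0-based half-open convention of
#' \code{\link{sample_vois}}.
#'
#' @param volume \code{\link{image_stack}} or 3D array (y, x, z).
#' @param spec one-row data.frame (or list) with \code{x}, \code{z},
#'   \code{y}, \code{size}.
#' @return 3D array of dimensions (size, size, size), axis order (y, x, z).
#' @export
extract_voi <- function(volume, spec) {
  vox <- if (inherits(volume, "image_stack")) volume$voxels else volume
  d <- dim(vox)
  s <- as.integer(spec$size[1L])
  x0 <- as.integer(spec$x[1L]); z0 <- as.integer(spec$z[1L])
  y0 <- as.integer(spec$y[1L])
  if (x0 < 0L || z0 < 0L || y0 < 0L ||
      y0 + s > d[1L] || x0 + s > d[2L] || z0 + s > d[3L])
    stop("VOI [", x0, ", ", z0, ", ", y0, ") + ", s,
         " lies outside the volume bounds")
  vox[(y0 + 1L):(y0 + s), (x0 + 1L):(x0 + s), (z0 + 1L):(z0 + s),
      drop = FALSE]
}
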