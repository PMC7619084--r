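#' Parameters of the layered OCT speckle phantom
#'
#' Builds the parameter set of the synthetic retina volume used to exercise
#' the texture pipeline. The phantom is a stack of flat layers (echoing the
#' retinal layers visible in a B-scan: medium, RNFL, GCL, IPL, INL, OPL, ONL,
#' IS/OS, RPE, sclera) with mean backscatter per layer, fully developed
#' multiplicative speckle (gamma, mean 1, shape \code{speckle_shape}), and,
#' inside the IPL only, a band-limited Gaussian random heterogeneity field
#' whose amplitude (\code{texture_gain}) and correlation length
#' (\code{texture_grain}) grow with the degeneration time \code{t}.
#'
#' The time course is encoded by a monotone schedule s(t) interpolated
#' through anchors at t = 0, 30, 60, 120 min with a small 0 to 30 step and a
#' large 30 to 60 step, so that early time points overlap in texture space
#' while early and late separate; \code{texture_gain} and
#' \code{texture_grain} are linear in s(t) between their endpoint values.
#' A per-volume lognormal jitter on the heterogeneity amplitude models
#' between-explant biological variability of the degeneration signal.
#'
#' @param t degeneration time in minutes (study values 0, 30, 60, 120;
#'   any value in [0, 120] is interpolated).
#' @param seed integer RNG seed; identical parameters and seed give a
#'   bit-identical volume.
#' @param dims volume dimensions c(ny depth, nx, nz) (default 128, 256, 256).
#' @param layer_boundaries strictly increasing depth indices ending each
#'   layer (last must equal ny).
#' @param layer_reflectivity mean backscatter per layer (0-255), same length
#'   as \code{layer_boundaries}.
#' @param layer_names layer labels; must contain "IPL".
#' @param speckle_shape gamma shape of the multiplicative speckle (default 6;
#'   smaller = noisier speckle).
#' @param gain_range IPL heterogeneity amplitude (intensity units) at
#'   t = 0 and t = 120.
#' @param grain_range IPL heterogeneity correlation length (voxels) at
#'   t = 0 and t = 120.
#' @param schedule_anchors,schedule_values monotone schedule s(t) (defaults:
#'   t = 0, 30, 60, 120 -> s = 0, 0.02, 0.96, 1).
#' @param jitter_sd lognormal sd of the per-volume jitter on
#'   \code{texture_gain} (default 0.03).
#' @param voi_size edge length the IPL must accommodate (default 30).
#' @return object of class \code{"phantom_params"}.
#' @export
phantom_params <- function(t = 0, seed = 1L,
                           dims = c(128L, 256L, 256L),
                           layer_boundaries = c(12L, 22L, 30L, 66L, 80L, 90L,
                                                104L, 110L, 116L, 128L),
                           layer_reflectivity = c(15, 190, 110, 80, 55, 120,
                                                  45, 200, 180, 40),
                           layer_names = c("medium", "RNFL", "GCL", "IPL",
                                           "INL", "OPL", "ONL", "IS/OS",
                                           "RPE", "sclera"),
                           speckle_shape = 6,
                           gain_range = c(8, 25),
                           grain_range = c(1.5, 1.9),
                           schedule_anchors = c(0, 30, 60, 120),
                           schedule_values = c(0, 0.02, 0.96, 1),
                           jitter_sd = 0.03,
                           voi_size = 30L) {
  if (t < min(schedule_anchors) || t > max(schedule_anchors))
    stop("'t' must lie within the schedule range [",
         min(schedule_anchors), ", ", max(schedule_anchors), "] minutes")
  if (any(diff(layer_boundaries) <= 0) || layer_boundaries[1L] <= 0)
    stop("'layer_boundaries' must be strictly increasing positive depths")
  if (utils::tail(layer_boundaries, 1L) != dims[1L])
    stop("last layer boundary must equal the volume depth ", dims[1L])
  if (length(layer_reflectivity) != length(layer_boundaries) ||
      length(layer_names) != length(layer_boundaries))
    stop("one reflectivity and one name per layer required")
  if (!"IPL" %in% layer_names) stop("'layer_names' must contain \"IPL\"")
  if (any(layer_reflectivity < 0 | layer_reflectivity > 255))
    stop("'layer_reflectivity' must lie in [0, 255]")
  if (speckle_shape <= 0) stop("'speckle_shape' must be positive")
  if (is.unsorted(schedule_values) || is.unsorted(schedule_anchors))
    stop("schedule must be monotone non-decreasing")
  if (diff(gain_range) < 0 || diff(grain_range) < 0)
    stop("gain/grain endpoints must be non-decreasing in t")
  s <- stats::approx(schedule_anchors, schedule_values, xout = t)$y
  structure(list(
    t = t, seed = as.integer(seed), dims = as.integer(dims),
    layer_boundaries = as.integer(layer_boundaries),
    layer_reflectivity = layer_reflectivity, layer_names = layer_names,
    speckle_shape = speckle_shape,
    gain_range = gain_range, grain_range = grain_range,
    schedule_anchors = schedule_anchors, schedule_values = schedule_values,
    texture_gain = gain_range[1L] + s * diff(gain_range),
    texture_grain = grain_range[1L] + s * diff(grain_range),
    jitter_sd = jitter_sd, voi_size = as.integer(voi_size)),
    class = "phantom_params")
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf(paste0("phantom_params: t = %g min, %d x %d x %d (y,x,z), ",
                     "%d layers\n  texture_gain = %.3g, texture_grain = %.3g",
                     " voxels, speckle shape = %g, seed = %d\n"),
              x$t, x$dims[1L], x$dims[2L], x$dims[3L],
              length(x$layer_boundaries), x$texture_gain, x$texture_grain,
              x$speckle_shape, x$seed))
  invisible(x)
}

# Evaluate code with a private, restored RNG state seeded from 'seed'.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Periodic 3D Gaussian smoothing by FFT; returns unit-variance field.
# The kernel is separable, so its 3D spectrum is the outer product of three
# 1D spectra (real, since the kernel is even) — one 3D FFT is saved.
smooth_field3 <- function(noise, sigma) {
  d <- dim(noise)
  if (sigma <= 0) return((noise - mean(noise)) / stats::sd(noise))
  kern1 <- function(n) {
    x <- if (n == 1L) 0 else if (n == 2L) c(0, 1)
         else c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
  }
  spec1 <- function(n) Re(stats::fft(kern1(n)))
  K <- outer(outer(spec1(d[1L]), spec1(d[2L])), spec1(d[3L]))
  dim(K) <- d
  f <- Re(stats::fft(stats::fft(noise) * K, inverse = TRUE)) / prod(d)
  (f - mean(f)) / stats::sd(f)
}

#' Generate a layered OCT speckle phantom volume
#'
#' Renders the forward model described in \code{\link{phantom_params}}:
#' per-layer mean reflectivity, IPL heterogeneity field scaled by
#' \code{texture_gain}, multiplicative gamma speckle, 8-bit quantization.
#' Deterministic given (params, seed). The GLCM contrast and entropy of the
#' IPL increase in expectation with the degeneration time t.
#'
#' @param params object of class \code{"phantom_params"}.
#' @return list with components \code{stack} (\code{\link{image_stack}}),
#'   \code{labels} (integer array of per-voxel layer ids),
#'   \code{layer_names}, \code{ipl_mask} (logical array), and \code{params}.
#' @export
generate_volume <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  d <- params$dims
  bnd <- params$layer_boundaries
  ipl_id <- match("IPL", params$layer_names)
  ipl_lo <- if (ipl_id == 1L) 1L else bnd[ipl_id - 1L] + 1L
  ipl_hi <- bnd[ipl_id]
  thick <- ipl_hi - ipl_lo + 1L
  if (thick < params$voi_size || d[2L] < params$voi_size ||
      d[3L] < params$voi_size)
    stop("volume too small to contain a ", params$voi_size, "^3 VOI inside ",
         "the IPL: IPL thickness ", thick, ", lateral dims ", d[2L], " x ",
         d[3L])

  layer_of_y <- findInterval(seq_len(d[1L]), bnd + 0.5) + 1L
  with_seed(params$seed, {
    # per-volume biological variability acts on the degeneration signal
    jit <- exp(stats::rnorm(1L, 0, params$jitter_sd))
    refl <- params$layer_reflectivity[layer_of_y]
    vol <- array(refl, dim = d)      # recycles along y (first dim)
    gain <- params$texture_gain * jit
    if (gain > 0) {
      slab_d <- c(thick, d[2L], d[3L])
      noise <- array(stats::rnorm(prod(slab_d)), dim = slab_d)
      field <- smooth_field3(noise, params$texture_grain)
      vol[ipl_lo:ipl_hi, , ] <- vol[ipl_lo:ipl_hi, , ] + gain * field
    }
    if (is.finite(params$speckle_shape)) {
      speck <- stats::rgamma(prod(d), shape = params$speckle_shape,
                             rate = params$speckle_shape)
      vol <- vol * speck
    }                                   # shape = Inf: speckle-free limit
  })
  labels <- array(layer_of_y, dim = d)
  list(stack = image_stack(round_half_away(vol)),
       labels = labels,
       layer_names = params$layer_names,
       ipl_mask = array(layer_of_y == ipl_id, dim = d),
       params = params)
}

#' Parameters of the synthetic edge / graticule target
#'
#' Models the micrograph of a calibration slide: bright and dark lines of
#' intensities \code{i_max} / \code{i_min}, optionally a single step edge
#' (\code{period = NULL}), blurred by a Gaussian point-spread function of
#' width \code{psf_sigma} and corrupted by additive Gaussian noise.
#'
#' @param i_max,i_min peak and trough intensity (0-255, i_min <= i_max).
#' @param psf_sigma Gaussian PSF sigma in pixels (>= 0).
#' @param period graticule line period in pixels (half bright, half dark);
#'   \code{NULL} for a single step edge at the image centre.
#' @param noise_sd additive Gaussian noise sd in intensity units.
#' @param seed integer RNG seed (used only when \code{noise_sd > 0}).
#' @param width,height image size in pixels.
#' @return object of class \code{"edge_target_params"}.
#' @export
edge_target_params <- function(i_max = 255, i_min = 57, psf_sigma = 0,
                               period = NULL, noise_sd = 0, seed = 1L,
                               width = 512L, height = 128L) {
  if (i_min < 0 || i_max > 255 || i_min > i_max)
    stop("need 0 <= i_min <= i_max <= 255")
  if (psf_sigma < 0) stop("'psf_sigma' must be >= 0")
  if (!is.null(period) && period < 2) stop("'period' must be >= 2 pixels")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(i_max = i_max, i_min = i_min, psf_sigma = psf_sigma,
                 period = period, noise_sd = noise_sd,
                 seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height)),
            class = "edge_target_params")
}

# Discrete Gaussian blur of a 1D profile, replicate padding.
blur_profile <- function(v, sigma) {
  if (sigma <= 0) return(v)
  r <- ceiling(4 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  padded <- c(rep(v[1L], r), v, rep(v[length(v)], r))
  stats::filter(padded, k, sides = 2)[(r + 1):(r + length(v))]
}

#' Generate a synthetic edge or graticule micrograph
#'
#' With zero blur and zero noise the image extrema equal exactly
#' \code{i_max} and \code{i_min}. Intensity varies along columns; rows are
#' replicated scan lines (independent noise per pixel when
#' \code{noise_sd > 0}).
#'
#' @param params object of class \code{"edge_target_params"}.
#' @return integer matrix (height x width) of 8-bit intensities.
#' @export
generate_edge_target <- function(params) {
  stopifnot(inherits(params, "edge_target_params"))
  w <- params$width; h <- params$height
  profile <- if (is.null(params$period)) {
    c(rep(params$i_min, w %/% 2), rep(params$i_max, w - w %/% 2))
  } else {
    half <- params$period / 2
    ifelse(((seq_len(w) - 1) %/% half) %% 2 == 0,
           params$i_min, params$i_max)
  }
  profile <- as.numeric(blur_profile(profile, params$psf_sigma))
  img <- matrix(profile, nrow = h, ncol = w, byrow = TRUE)
  if (params$noise_sd > 0)
    img <- img + with_seed(params$seed,
                           matrix(stats::rnorm(h * w, 0, params$noise_sd),
                                  nrow = h))
  round_half_away(img)
}
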