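#' Resolve a pipeline run configuration
#'
#' Reads a YAML configuration (or takes a nested list), fills every missing
#' key from the package defaults, validates the result and stamps it with a
#' content hash. Every pipeline command (\code{\link{cmd_phantom}},
#' \code{\link{cmd_texture}}, \code{\link{cmd_mtf}},
#' \code{\link{cmd_classify}}) takes a resolved config, writes its outputs
#' under \code{output_dir}, writes the resolved config beside them and
#' prefixes every delimited output with the config hash, so a run is
#' reproducible from its output directory alone.
#'
#' @param config path to a YAML file, or a nested list of overrides.
#' @param overrides optional second list applied on top (CLI flags).
#' @return object of class \code{"run_config"} (a nested list with
#'   attribute \code{hash}).
#' @export
load_run_config <- function(config = list(), overrides = list()) {
  defaults <- list(
    output_dir = "octtex_out",
    seed = 1L,
    phantom = list(time_points = c(0, 30, 60, 120), n_retinas = 3L,
                   images_per_retina = 2L, params = list()),
    voi = list(n_per_image = 10L, size = 30L),
    glcm = list(levels = 64L, distance = 1L, entropy_base = "ln",
                homogeneity = "squared"),
    preproc = list(line_filter = FALSE, notch_width = 3),
    ml = list(use_pca = FALSE, k_folds = 5L, C = 1),
    mtf = list(percentiles = c(0.05, 0.95), pad_factor = 4L,
               i_max_object = 255, i_min_object = 57,
               i_max_image = 255, i_min_image = 138,
               psf_sigma = 2, period = 64, noise_sd = 0))
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_lists(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(merge_lists(defaults, config), overrides)
  stopifnot(cfg$voi$size >= 1, cfg$glcm$levels >= 2, cfg$ml$k_folds >= 2)
  # hash of the scientific settings only, so the same analysis in a
  # different output directory is recognisably identical
  attr(cfg, "hash") <- digest::digest(cfg[setdiff(names(cfg), "output_dir")],
                                      algo = "sha1")
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) attr(cfg, "hash")

write_resolved_config <- function(cfg) {
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  plain <- unclass(cfg); attributes(plain) <- list(names = names(plain))
  yaml::write_yaml(plain, file.path(cfg$output_dir, "resolved_config.yaml"))
}

# delimited text with a '#'-comment hash header; read back with read_table_out
write_table_out <- function(df, cfg, name) {
  path <- file.path(cfg$output_dir, name)
  con <- file(path, "w")
  writeLines(sprintf("# config_hash: %s", config_hash(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

#' Read a pipeline output table
#' @param path CSV written by a \code{cmd_*} command.
#' @return data.frame; the config hash is in attribute \code{config_hash}.
#' @export
read_table_out <- function(path) {
  first <- readLines(path, n = 1L)
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "config_hash") <- sub("^# config_hash: ", "", first)
  df
}

#' Generate phantom volumes on disk
#'
#' Writes one multi-page 8-bit TIFF per phantom volume (and one per layer
#' mask, scaled by layer id) plus a manifest CSV, following the study design
#' in the config.
#'
#' @param config resolved \code{\link{load_run_config}} object (or anything
#'   it accepts).
#' @return manifest data.frame, invisibly.
#' @export
cmd_phantom <- function(config = list()) {
  cfg <- load_run_config(config)
  write_resolved_config(cfg)
  rows <- list(); img <- 0L
  for (t in cfg$phantom$time_points)
    for (r in seq_len(cfg$phantom$n_retinas))
      for (im in seq_len(cfg$phantom$images_per_retina)) {
        img <- img + 1L
        sub_seed <- (cfg$seed * 10007L + img * 131L) %% 2147483647L
        vol <- generate_volume(do.call(phantom_params, c(
          list(t = t, seed = sub_seed, voi_size = cfg$voi$size),
          cfg$phantom$params)))
        vfile <- sprintf("phantom_t%03d_r%d_i%d.tif", t, r, im)
        mfile <- sub("\\.tif$", "_mask.tif", vfile)
        write_tiff_stack(vol$stack, file.path(cfg$output_dir, vfile))
        n_layers <- length(vol$layer_names)
        write_tiff_stack(round_half_away(vol$labels * (255 / n_layers)),
                         file.path(cfg$output_dir, mfile))
        rows[[img]] <- data.frame(file = vfile, mask_file = mfile,
                                  time_point = t, retina = r, image = im,
                                  seed = sub_seed,
                                  ipl_label = match("IPL", vol$layer_names),
                                  n_layers = n_layers)
      }
  manifest <- do.call(rbind, rows)
  write_table_out(manifest, cfg, "manifest.csv")
  invisible(manifest)
}

#' Extract the texture feature table
#'
#' If a \code{manifest.csv} from \code{\link{cmd_phantom}} is present in the
#' output directory, volumes are read back from TIFF (applying the FFT
#' stripe filter to every B-scan when \code{preproc$line_filter} is true);
#' otherwise phantoms are generated in memory. VOIs are sampled in the IPL
#' and one 20-feature row per VOI is written to \code{features.csv}.
#'
#' @inheritParams cmd_phantom
#' @return feature data.frame, invisibly.
#' @export
cmd_texture <- function(config = list()) {
  cfg <- load_run_config(config)
  write_resolved_config(cfg)
  manifest_path <- file.path(cfg$output_dir, "manifest.csv")
  if (file.exists(manifest_path)) {
    manifest <- read_table_out(manifest_path)
    rows <- lapply(seq_len(nrow(manifest)), function(k) {
      m <- manifest[k, ]
      stk <- read_tiff_stack(file.path(cfg$output_dir, m$file))
      if (isTRUE(cfg$preproc$line_filter)) {
        for (z in seq_len(dim(stk$voxels)[3L]))
          stk$voxels[, , z] <- fft_line_filter(
            stk$voxels[, , z], notch_width = cfg$preproc$notch_width)
      }
      mask_stack <- read_tiff_stack(file.path(cfg$output_dir, m$mask_file))
      labels <- round_half_away(mask_stack$voxels / (255 / m$n_layers),
                                clip = FALSE)
      ipl <- array(labels == m$ipl_label, dim = dim(labels))
      vois <- sample_vois(stk, ipl, cfg$voi$n_per_image,
                          seed = m$seed + 1L, size = cfg$voi$size,
                          source_image_id = m$file,
                          time_point = m$time_point)
      feats <- t(vapply(seq_len(nrow(vois)), function(i)
        voi_feature_vector(extract_voi(stk, vois[i, ]),
                           levels = cfg$glcm$levels,
                           distance = cfg$glcm$distance,
                           entropy_base = cfg$glcm$entropy_base,
                           homogeneity = cfg$glcm$homogeneity),
        numeric(20L)))
      colnames(feats) <- glcm_feature_names()
      cbind(data.frame(time_point = m$time_point, retina = m$retina,
                       source_image_id = m$file,
                       x = vois$x, z = vois$z, y = vois$y),
            as.data.frame(feats))
    })
    tab <- do.call(rbind, rows)
  } else {
    tab <- phantom_study(seed = cfg$seed,
                         time_points = cfg$phantom$time_points,
                         n_retinas = cfg$phantom$n_retinas,
                         images_per_retina = cfg$phantom$images_per_retina,
                         vois_per_image = cfg$voi$n_per_image,
                         voi_size = cfg$voi$size,
                         levels = cfg$glcm$levels,
                         distance = cfg$glcm$distance,
                         params_fn = function(t, seed)
                           do.call(phantom_params, c(
                             list(t = t, seed = seed,
                                  voi_size = cfg$voi$size),
                             cfg$phantom$params)))
  }
  write_table_out(tab, cfg, "features.csv")
  invisible(tab)
}

#' Run the transparency (MTF) assay on synthetic targets
#'
#' Generates the control (bare calibration slide) and through-tissue
#' graticule micrographs from the config intensities, measures their
#' modulation depths, forms the contrast-transfer ratio, and computes the
#' MTF curve of a matching edge target. Writes \code{mtf_curve.csv} and
#' \code{mtf_summary.csv}.
#'
#' @inheritParams cmd_phantom
#' @return summary data.frame, invisibly.
#' @export
cmd_mtf <- function(config = list()) {
  cfg <- load_run_config(config)
  write_resolved_config(cfg)
  m <- cfg$mtf
  obj_img <- generate_edge_target(edge_target_params(
    i_max = m$i_max_object, i_min = m$i_min_object, psf_sigma = m$psf_sigma,
    period = m$period, noise_sd = m$noise_sd, seed = cfg$seed))
  img_img <- generate_edge_target(edge_target_params(
    i_max = m$i_max_image, i_min = m$i_min_image, psf_sigma = m$psf_sigma,
    period = m$period, noise_sd = m$noise_sd, seed = cfg$seed + 1L))
  md_o <- measure_graticule_modulation(obj_img, percentiles = m$percentiles)
  md_i <- measure_graticule_modulation(img_img, percentiles = m$percentiles)
  ratio <- mtf_ratio(md_i, md_o)
  edge <- generate_edge_target(edge_target_params(
    i_max = m$i_max_object, i_min = m$i_min_object, psf_sigma = m$psf_sigma,
    period = NULL, noise_sd = m$noise_sd, seed = cfg$seed + 2L))
  curve <- edge_target_mtf(edge, pad_factor = m$pad_factor)
  write_table_out(data.frame(frequency = curve$frequencies,
                             mtf = curve$values), cfg, "mtf_curve.csv")
  summary <- data.frame(
    i_max_object = md_o$i_max, i_min_object = md_o$i_min, m_object = md_o$m,
    i_max_image = md_i$i_max, i_min_image = md_i$i_min, m_image = md_i$m,
    mtf_fx = ratio)
  write_table_out(summary, cfg, "mtf_summary.csv")
  invisible(summary)
}

#' Classify the feature table and report confusion statistics
#'
#' Reads \code{features.csv} (running \code{\link{cmd_texture}} first if it
#' is missing), cross-validates the linear SVM with and without the PCA
#' projection, and writes confusion counts, row-percentage matrices in the
#' summary-table layout (with TPR/FPR columns), and a one-row statistics
#' summary.
#'
#' @inheritParams cmd_phantom
#' @return list with both \code{\link{confusion_matrix}} objects, invisibly.
#' @export
cmd_classify <- function(config = list()) {
  cfg <- load_run_config(config)
  write_resolved_config(cfg)
  fpath <- file.path(cfg$output_dir, "features.csv")
  tab <- if (file.exists(fpath)) read_table_out(fpath) else cmd_texture(cfg)
  feats <- as.matrix(tab[, glcm_feature_names()])
  y <- factor(tab$time_point)
  out <- list()
  for (variant in c("svm", "pca_svm")) {
    cm <- cross_validate(feats, y, use_pca = variant == "pca_svm",
                         k_folds = cfg$ml$k_folds, C = cfg$ml$C,
                         seed = cfg$seed)
    st <- confusion_stats(cm)
    write_table_out(as.data.frame(cm$counts), cfg,
                    sprintf("confusion_counts_%s.csv", variant))
    layout <- cbind(as.data.frame(round_half_up(cm$percent, 1L)),
                    TPR = st$tpr, FPR = st$fpr)
    write_table_out(cbind(true_class = rownames(cm$percent), layout), cfg,
                    sprintf("confusion_percent_%s.csv", variant))
    out[[variant]] <- cm
  }
  write_table_out(data.frame(
    mean_accuracy_svm = confusion_stats(out$svm)$mean_accuracy,
    mean_accuracy_pca_svm = confusion_stats(out$pca_svm)$mean_accuracy,
    n_voi = nrow(tab)), cfg, "classification_summary.csv")
  invisible(out)
}
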