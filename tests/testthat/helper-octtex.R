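# Independent brute-force GLCM oracle: explicit double loop over all pixel
# pairs, with its own quantization. Kept deliberately naive.
glcm_brute <- function(slice, direction, distance = 1L, levels = 8L) {
  q <- pmin(floor(slice * levels / 256), levels - 1)
  off <- switch(as.character(direction),
                "0" = c(0, distance), "90" = c(-distance, 0),
                "180" = c(0, -distance), "270" = c(distance, 0))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        i <- q[r, cc]; j <- q[r2, c2]
        counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# A small, fast phantom for unit tests: 4 layers, 64x64 lateral, IPL 32
# voxels thick, 16^3 VOIs.
small_params <- function(t = 0, seed = 1L, ...) {
  phantom_params(t = t, seed = seed,
                 dims = c(48L, 64L, 64L),
                 layer_boundaries = c(6L, 10L, 42L, 48L),
                 layer_reflectivity = c(15, 110, 80, 40),
                 layer_names = c("medium", "GCL", "IPL", "sclera"),
                 voi_size = 16L, ...)
}

# mean GLCM feature over freshly sampled VOIs of one small volume
small_voi_features <- function(vol, n = 5L, seed = 7L, size = 16L) {
  vois <- sample_vois(vol$stack, vol$ipl_mask, n, seed = seed, size = size)
  t(vapply(seq_len(n), function(k)
    voi_feature_vector(extract_voi(vol$stack, vois[k, ])), numeric(20L)))
}

# Table 1 row-percentage matrices (inputs to the confusion statistics)
table1_svm <- matrix(c(75, 25, 0, 0,
                       23, 77, 0, 0,
                       0, 0, 97, 3,
                       0, 0, 4, 96), nrow = 4, byrow = TRUE,
                     dimnames = list(c("0", "30", "60", "120"),
                                     c("0", "30", "60", "120")))
table1_pca_svm <- matrix(c(70, 30, 0, 0,
                           28, 72, 0, 0,
                           0, 0, 92, 8,
                           0, 0, 7, 93), nrow = 4, byrow = TRUE,
                         dimnames = dimnames(table1_svm))
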