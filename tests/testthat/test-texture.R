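test_that("GLCM of the hand-enumerated 2x2 slice has a single off-diagonal entry", {
  # slice (rows x cols) = [[0,1],[0,1]] in grey-level codes, levels = 2
  slice <- matrix(c(0L, 0L, 1L, 1L), nrow = 2)
  g <- compute_glcm(slice, direction = 0, levels = 2, quantized = TRUE)
  expect_equal(g$p, matrix(c(0, 0, 1, 0), nrow = 2))   # p(0,1) = 1
  f <- glcm_features(g)
  expect_equal(unname(f[c("energy", "contrast", "entropy", "homogeneity")]),
               c(1, 1, 0, 0.5))
  expect_true(is.na(f["correlation"]))
})

test_that("constant slice gives a degenerate diagonal GLCM with flagged correlation", {
  g <- compute_glcm(matrix(100, 5, 5), direction = 90, levels = 64)
  expect_equal(sum(g$p), 1)
  k <- quantize_levels(100, 64) + 1L
  expect_equal(g$p[k, k], 1)
  f <- glcm_features(g)
  expect_equal(unname(f[c("energy", "contrast", "entropy", "homogeneity")]),
               c(1, 0, 0, 1))
  expect_true(is.na(f["correlation"]))
  expect_true(attr(f, "undefined_correlation"))
})

test_that("uniform co-occurrence distribution matches the closed forms", {
  gu <- structure(list(p = matrix(1 / 16, 4, 4), direction = 0,
                       distance = 1L, levels = 4L, n_pairs = 16L),
                  class = "glcm")
  f <- glcm_features(gu)
  expect_equal(unname(f["energy"]), 1 / 16)
  expect_equal(unname(f["entropy"]), log(16))
  expect_equal(unname(glcm_features(gu, entropy_base = "log2")["entropy"]), 4)
})

test_that("compute_glcm equals the brute-force pair enumeration", {
  set.seed(11)
  for (rep in 1:50) {
    slice <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    d <- sample(1:3, 1)
    for (dir in c(0, 90, 180, 270)) {
      g <- compute_glcm(slice, direction = dir, distance = d, levels = 8)
      expect_equal(g$p, glcm_brute(slice, dir, d, 8), tolerance = 1e-12)
    }
  }
})

test_that("GLCM probabilities sum to one and errors trigger on undersized slices", {
  set.seed(2)
  g <- compute_glcm(matrix(runif(30, 0, 255), 5, 6), direction = 270)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)
  expect_error(compute_glcm(matrix(1, 1, 3), direction = 90),
               "no pixel pair")
  expect_error(compute_glcm(matrix(1, 3, 3), direction = 0, distance = 5),
               "no pixel pair")
})

test_that("VOI feature vector has 20 named entries in the 5 x 4 grid", {
  set.seed(3)
  block <- array(sample(0:255, 6^3, replace = TRUE), dim = c(6, 6, 6))
  v <- voi_feature_vector(block)
  expect_length(v, 20)
  expect_identical(names(v), glcm_feature_names())
  expect_identical(names(v)[1:5],
                   c("energy_0", "contrast_0", "entropy_0", "correlation_0",
                     "homogeneity_0"))
})

test_that("constant block yields contrast 0 and energy 1 in all four directions", {
  block <- array(42, dim = c(4, 4, 4))
  v <- suppressWarnings(voi_feature_vector(block))
  expect_equal(unname(v[paste0("contrast_", c(0, 90, 180, 270))]),
               rep(0, 4))
  expect_equal(unname(v[paste0("energy_", c(0, 90, 180, 270))]), rep(1, 4))
})

test_that("opposite directions give transposed GLCMs, hence equal features", {
  set.seed(4)
  block <- array(sample(0:255, 10^3, replace = TRUE), dim = c(10, 10, 10))
  v <- voi_feature_vector(block)
  for (f in c("energy", "contrast", "entropy", "correlation", "homogeneity")) {
    expect_equal(v[paste0(f, "_0")], v[paste0(f, "_180")],
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(v[paste0(f, "_90")], v[paste0(f, "_270")],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  # and directly on a single slice
  sl <- matrix(sample(0:255, 49, replace = TRUE), 7, 7)
  g0 <- compute_glcm(sl, 0, levels = 8)
  g180 <- compute_glcm(sl, 180, levels = 8)
  expect_equal(g0$p, t(g180$p), tolerance = 1e-12)
})

test_that("contrast and homogeneity are invariant to a whole-bin intensity shift", {
  set.seed(5)
  block <- array(sample(0:200, 5^3, replace = TRUE), dim = c(5, 5, 5))
  shift <- 2 * (256 / 64)                 # two full bins at G = 64
  v1 <- voi_feature_vector(block)
  v2 <- voi_feature_vector(block + shift)
  dirs <- c(0, 90, 180, 270)
  expect_equal(v1[paste0("contrast_", dirs)], v2[paste0("contrast_", dirs)],
               tolerance = 1e-12)
  expect_equal(v1[paste0("homogeneity_", dirs)],
               v2[paste0("homogeneity_", dirs)], tolerance = 1e-12)
})

test_that("quantization uses fixed bin edges over [0, 255]", {
  expect_equal(quantize_levels(c(0, 3.9, 4, 255), 64), c(0, 0, 1, 63))
  expect_error(quantize_levels(c(-1, 5)), "\\[0, 255\\]")
  expect_error(quantize_levels(256), "\\[0, 255\\]")
})
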