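test_that("ESF of an ideal step is the exact step and flat images are rejected", {
  img <- generate_edge_target(edge_target_params(i_max = 255, i_min = 57,
                                                 psf_sigma = 0, width = 40,
                                                 height = 8))
  expect_equal(max(img), 255)
  expect_equal(min(img), 57)
  esf <- edge_spread_function(img)
  expect_equal(esf$values, c(rep(57, 20), rep(255, 20)))
  expect_error(edge_spread_function(matrix(100, 8, 40)), "no edge detected")
})

test_that("ESF of a Gaussian-blurred step follows the Gaussian CDF profile", {
  sig <- 2
  img <- generate_edge_target(edge_target_params(i_max = 255, i_min = 57,
                                                 psf_sigma = sig,
                                                 width = 64, height = 16))
  esf <- edge_spread_function(img)
  x <- seq_along(esf$values)
  expected <- 57 + 198 * pnorm((x - 32.5) / sig)
  expect_lt(max(abs(esf$values - expected)), 1)   # 8-bit quantization bound
})

test_that("LSF handles the delta, ramp and Gaussian cases and has unit area", {
  step <- structure(list(values = c(rep(0, 10), rep(1, 10)), spacing = 1),
                    class = "intensity_profile")
  lsf <- line_spread_function(step)
  expect_equal(sum(lsf$values), 1)
  expect_equal(sum(lsf$values > 0), 2)   # central difference spans the jump
  ramp <- structure(list(values = seq(0, 30), spacing = 1),
                    class = "intensity_profile")
  lr <- line_spread_function(ramp)
  expect_equal(unname(diff(range(lr$values))), 0, tolerance = 1e-12)
  gauss_esf <- structure(list(values = pnorm(seq(-20, 20), sd = 2),
                              spacing = 1), class = "intensity_profile")
  lg <- line_spread_function(gauss_esf)
  expect_equal(sum(lg$values), 1)
  gn <- dnorm(seq(-20, 20), sd = 2)
  expect_equal(lg$values, gn / sum(gn), tolerance = 0.05,
               ignore_attr = TRUE)
  expect_error(line_spread_function(structure(
    list(values = rep(3, 10), spacing = 1), class = "intensity_profile")),
    "flat profile")
})

test_that("MTF closed forms: impulse, Gaussian, and twin-impulse LSFs", {
  imp <- structure(list(values = c(rep(0, 8), 1, rep(0, 8)), spacing = 1),
                   class = "intensity_profile")
  mc <- mtf_curve(imp)
  expect_equal(mc$values, rep(1, length(mc$values)))
  expect_equal(mc$values[1], 1)

  for (sig in c(1, 2, 4)) {
    xs <- seq(-8 * sig, 8 * sig)
    lsf <- structure(list(values = dnorm(xs, sd = sig), spacing = 1),
                     class = "intensity_profile")
    mg <- mtf_curve(lsf, pad_factor = 4)
    truth <- exp(-2 * pi^2 * sig^2 * mg$frequencies^2)
    expect_lt(sqrt(mean((mg$values - truth)^2)), 0.02)
  }

  s <- 6
  two <- numeric(32); two[c(4, 4 + s)] <- 1
  mt <- mtf_curve(structure(list(values = two, spacing = 1),
                            class = "intensity_profile"))
  expect_equal(mt$values, abs(cos(pi * mt$frequencies * s)),
               tolerance = 1e-10)
  expect_error(mtf_curve(structure(list(values = rep(0, 8), spacing = 1),
                                   class = "intensity_profile")),
               "identically zero")
})

test_that("modulation depth reproduces the printed intensity arithmetic", {
  expect_equal(modulation_depth(255, 57)$m, 198 / 312)
  expect_equal(modulation_depth(255, 138)$m, 117 / 393)
  expect_equal(modulation_depth(80, 80)$m, 0)
  expect_error(modulation_depth(10, 20), "exceed")
  expect_error(modulation_depth(0, 0), "both intensities")
})

test_that("contrast-transfer ratio behaves at the worked values and the bounds", {
  m_o <- modulation_depth(255, 57)
  m_i <- modulation_depth(255, 138)
  expect_equal(mtf_ratio(m_i, m_o), (117 / 393) / (198 / 312))
  expect_equal(mtf_ratio(m_i, m_o), 0.4691, tolerance = 1e-4)
  expect_equal(mtf_ratio(m_o, m_o), 1)
  expect_equal(mtf_ratio(modulation_depth(50, 50), m_o), 0)
  expect_error(mtf_ratio(m_i, modulation_depth(50, 50)), "undefined")
})

test_that("graticule modulation measurement is exact noiseless and robust to noise", {
  grat <- generate_edge_target(edge_target_params(i_max = 255, i_min = 57,
                                                  period = 64, width = 512,
                                                  height = 64))
  expect_equal(measure_graticule_modulation(grat)$m, 198 / 312,
               tolerance = 1e-6)
  noisy <- generate_edge_target(edge_target_params(i_max = 255, i_min = 57,
                                                   period = 64, width = 512,
                                                   height = 64, noise_sd = 2,
                                                   seed = 9))
  expect_lt(abs(measure_graticule_modulation(noisy)$m - 198 / 312), 0.02)
  expect_warning(m0 <- measure_graticule_modulation(matrix(100, 16, 16)),
                 "flat image")
  expect_equal(m0$m, 0)
})

test_that("a wider PSF degrades the measured MTF pointwise", {
  curves <- lapply(c(0.5, 1, 2, 4), function(s)
    edge_target_mtf(generate_edge_target(edge_target_params(psf_sigma = s))))
  for (k in 1:3)
    expect_true(all(curves[[k + 1]]$values <=
                      curves[[k]]$values + 0.02))
})

test_that("the edge-target pipeline recovers the analytic Gaussian MTF", {
  for (sig in c(1, 2, 4)) {
    img <- generate_edge_target(edge_target_params(i_max = 255, i_min = 57,
                                                   psf_sigma = sig))
    mc <- edge_target_mtf(img)
    truth <- exp(-2 * pi^2 * sig^2 * mc$frequencies^2)
    expect_lt(sqrt(mean((mc$values - truth)^2)), 0.02)
  }
})

test_that("repeated noisy acquisitions give MTF ratios stable to within 1%", {
  ratios <- vapply(c(21, 22), function(s) {
    obj <- generate_edge_target(edge_target_params(255, 57, psf_sigma = 1,
                                                   period = 64, noise_sd = 2,
                                                   seed = s))
    img <- generate_edge_target(edge_target_params(255, 138, psf_sigma = 1,
                                                   period = 64, noise_sd = 2,
                                                   seed = s + 100))
    mtf_ratio(measure_graticule_modulation(img),
              measure_graticule_modulation(obj))
  }, numeric(1))
  expect_lt(abs(ratios[1] - ratios[2]) / ratios[1], 0.01)
})
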