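# octtex

Speckle texture and transparency analysis of OCT retinal volumes.

Early retinal ganglion cell (RGC) degeneration — dendritic pruning and
organelle fragmentation after axon injury — changes how the inner plexiform
layer (IPL) scatters coherent light before any structure visible at OCT
resolution changes. `octtex` quantifies that signal in two complementary
ways, for researchers working with ex-vivo retinal explant models of optic
nerve injury:

* **Texture arm.** Random 30×30×30-voxel volumes of interest (VOIs) are
  sampled inside the IPL of an 8-bit OCT volume (anchored at the IPL/GCL
  border, vessels excludable by mask). Each VOI yields the grey-level
  co-occurrence matrix (GLCM) features

  energy = Σ p²ᵢⱼ, contrast = Σ (i−j)² pᵢⱼ, entropy = −Σ pᵢⱼ ln pᵢⱼ,
  correlation = Σ (i−μᵢ)(j−μⱼ) pᵢⱼ / (σᵢσⱼ), homogeneity = Σ pᵢⱼ / (1+(i−j)²)

  in four directions (0°, 90°, 180°, 270°), a 20-dimensional vector per
  VOI. Time after axotomy (0, 30, 60, 120 min) is classified by a linear
  SVM, optionally after PCA to two components, with stratified k-fold
  cross-validation and confusion statistics (per-class TPR/FPR, mean
  accuracy, pairwise false-negative rates).

* **Transparency arm.** The modulation transfer function of a calibration
  graticule imaged with and without the explant:
  MTF(fx) = M_I(fx)/M_O(fx) with M(fx) = (Imax − Imin)/(Imax + Imin),
  plus the full MTF(ν) curve from the edge-spread → line-spread → |FFT|
  chain. A stable ratio across the imaging window shows the texture signal
  is not an opacification artefact.

A synthetic layered speckle **phantom** with a degeneration-time parameter
drives every stage in tests and examples, so the package runs with no
microscope data; multi-page 8-bit TIFF I/O and an FFT stripe-artefact
filter connect it to real acquisitions.

## Worked example

```r
library(octtex)

## transparency arm: the printed worked intensities
m_control <- modulation_depth(255, 57)   # bare calibration slide
m_explant <- modulation_depth(255, 138)  # imaged through the explant
m_control
#> modulation depth m = 0.6346 (Imax = 255, Imin = 57)
m_explant
#> modulation depth m = 0.2977 (Imax = 255, Imin = 138)
mtf_ratio(m_explant, m_control)
#> [1] 0.4691187

## texture arm on the phantom (about two minutes at full scale)
study <- phantom_study(seed = 1)          # 240 VOIs, 4 time points
fit <- texture_svm(time_point ~ ., seed = 1,
                   data = study[, c("time_point", glcm_feature_names())])
fit
#> Texture time-point classifier (linear SVM on raw features)
#>   classes: 0, 30, 60, 120; n = 240 VOIs
#>   5-fold cross-validated mean accuracy: 54.2%
summary(fit)$stats$pairwise_fnr["0", "30"]
#> [1] 40
pairwise_cv_accuracy(as.matrix(study[, glcm_feature_names()]),
                     study$time_point, c(0, 60), seed = 1)
#> [1] 100
```

The pattern, not the headline number, is the result: baseline vs 30 min
barely separate (pairwise accuracy well under 75%), early vs late separate
essentially perfectly, and 60 vs 120 min confuse again — the block
structure expected when texture drifts quickly between 30 and 60 min and
slowly elsewhere. PCA before the SVM does not improve discrimination.
`plot(fit, study)` shows the four clusters in the PC1/PC2 plane.

Fed the published 4×4 classification table itself, the same summary
machinery returns its statistics exactly (mean accuracy 86.3%, early
pairwise FNR 24%):

```r
confusion_stats(rbind(c(75, 25, 0, 0), c(23, 77, 0, 0),
                      c(0, 0, 97, 3), c(0, 0, 4, 96)))$mean_accuracy
#> [1] 86.3
```

## Pipeline commands

`cmd_phantom()`, `cmd_texture()`, `cmd_mtf()` and `cmd_classify()` run the
stages against a YAML config and an output directory (volumes and masks as
multi-page TIFF, tables as hashed CSV); `inst/cli/octtex.R` is a thin
Rscript wrapper (`Rscript inst/cli/octtex.R classify --config run.yaml`).

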