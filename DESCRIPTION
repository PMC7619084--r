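Package: octtex
Title: Speckle Texture and Transparency Analysis of OCT Retinal Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies early retinal-ganglion-cell degeneration signals in
    optical coherence tomography (OCT) volumes of the inner plexiform layer.
    Provides grey-level co-occurrence matrix (Haralick) texture features in
    four directions, random 30x30x30-voxel volume-of-interest sampling inside
    a layer mask, an FFT stripe-artefact filter, PCA plus linear-SVM
    time-point classification with cross-validated confusion statistics, and
    a modulation-transfer-function transparency assay (edge spread function,
    line spread function, MTF curve, and Michelson modulation-depth ratios).
    A layered speckle-phantom generator with a degeneration-time parameter
    makes the full pipeline testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    tiff,
    e1071,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
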