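Package: arttomo
Title: Parallel-Beam Tomographic Simulation and Algebraic Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for 2D parallel-beam
    computed tomography at desk scale. Generates analytic and lung-slice-like
    phantoms (mosaic low-attenuation patches, thick-walled airway rings,
    vessel lines), builds sparse strip- or line-model system matrices,
    forward projects to sinograms, injects Poisson low-dose noise through a
    Beer-Lambert count model, and reconstructs with the Kaczmarz algebraic
    reconstruction technique (ART), simultaneous iterative reconstruction
    (SIRT), smoothness-regularized least squares, and filtered back
    projection (FBP). Includes an image-quality suite (MSE, EMSE, ISNR,
    PSNR, SSIM, line profiles) and scripted experiments comparing
    limited-angle low-dose ART against FBP and tracing semi-convergence of
    iterative reconstruction.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
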