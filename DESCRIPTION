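Package: ssopr
Title: Structured-Light Tissue Oxygenation Imaging with SFDI and SSOP
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for spatial frequency domain
    imaging (SFDI) and single snapshot imaging of optical properties (SSOP)
    of tissue oxygen saturation (StO2). Provides a diffusion-approximation
    diffuse-reflectance forward model, a structured-illumination scene
    renderer with fringe-projection profilometry, three-phase and
    single-frame Fourier demodulation, phantom calibration, look-up-table
    inversion to absorption and reduced scattering coefficients,
    Beer-Lambert hemoglobin unmixing to StO2 maps, a synthetic
    hemi-hepatic-ischemia study generator, and the lobe-wise statistical
    analysis (two-way ANOVA with multiple comparisons, Pearson correlation,
    demarcation-line detection) used to quantify liver ischemia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    png,
    jsonlite,
    EBImage,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
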