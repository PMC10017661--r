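Package: ssopOx
Title: Single-Snapshot Imaging of Optical Properties and Tissue Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Spatial frequency domain imaging (SFDI) and single-snapshot
    imaging of optical properties (SSOP) processing for multispectral
    tissue oximetry. Implements diffusion-approximation and Monte-Carlo
    forward models of spatially modulated diffuse reflectance, lookup-table
    construction and per-pixel inversion to absorption and reduced
    scattering coefficients, three-phase and single-frame Fourier-filter
    demodulation, reference-phantom calibration, two-wavelength haemoglobin
    unmixing to oxygen saturation (StO2) maps, and the region-of-interest
    statistics used in perfusion studies. Includes a structured-illumination
    scene simulator (calibration phantom and an ischaemic-bowel digital
    phantom) so the whole pipeline is testable end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
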