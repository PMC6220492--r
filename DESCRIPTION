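Package: suteac
Title: Segmented-UTE Attenuation Correction for PET/MR Brain Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for MR-based attenuation correction of brain PET/MR data
    using dual-echo ultrashort-echo-time (UTE) images. Implements UTE
    template and tissue-probability-map construction, Gaussian-mixture
    tissue segmentation with spatial priors, R2* relaxometry mapping,
    generation of 511 keV attenuation-coefficient maps with fixed or
    R2*-derived continuous bone values, a desk-scale attenuated
    parallel-beam OSEM emission simulator, a synthetic dual-echo UTE head
    phantom generator with ground truth, and a full evaluation suite
    (Dice, false-positive/negative rates, difference maps, relative-error
    analysis, SVD representative histograms, Mann-Whitney tests).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    Matrix,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
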