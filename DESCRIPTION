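Package: petparam
Title: Parametric Quantification of Dynamic Brain PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracer kinetic quantification for dynamic brain PET with a
    reversible one-tissue compartment model and fractional blood volume.
    Provides weighted non-linear regression fits (1T2k_VB and the simplified
    reference tissue model), linearized estimators (plasma-input Logan,
    reference Logan, the multilinear reference tissue model family), basis
    function methods (receptor parametric mapping, SRTM2 with data-driven
    k2', and plasma-input spectral analysis with a blood-volume component),
    voxel-wise parametric image generation, and a validation layer with
    regression agreement, percent bias, test-retest repeatability and
    intraclass correlation. A synthetic-data module generates arterial input
    functions, regional time-activity curves, digital phantoms and paired
    test-retest sessions with count-based frame noise for end-to-end
    validation against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    pracma,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
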