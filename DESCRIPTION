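Package: petperf
Title: NEMA NU2 Performance Analysis for PET Scanners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for the NEMA NU2-07 positron emission
    tomography (PET) performance tests: tomographic spatial resolution
    (FWHM/FWTM of reconstructed point sources), system sensitivity by
    attenuation-free extrapolation over the five-aluminium-sleeve phantom,
    scatter fraction and noise equivalent count rate (NECR) from line-source
    sinogram profiles, count-loss and randoms-correction accuracy, and
    IEC body-phantom image quality (sphere contrast, background variability,
    lung residual). Includes calibrated synthetic phantom and acquisition
    generators so every stage can be exercised and validated without scanner
    data, plus a consolidated performance report with configurable
    acceptance limits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
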