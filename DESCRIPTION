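Package: stentsim
Title: In Silico Evaluation of Vascular Stent Appearance in CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates CT imaging of stented-vessel phantoms and quantifies
    stent appearance. A synthetic phantom generator rasterizes contrast-filled
    arteries carrying one or two metal stents inside a soft-tissue-equivalent
    cylinder; a linear system model (Gaussian point-spread function, slice
    averaging, detector-pixel binning, quantum noise) degrades the ground
    truth under configurable scanner presets, including a photon-counting and
    an energy-integrating geometry at two reconstruction fields of view.
    Measurement routines recover stent diameter by a peak-to-peak method on
    Hounsfield-unit line profiles, quantify strut blooming from half-maximum
    inner and outer areas, and score inter-stent distinction from the relative
    peak-to-trough depth between adjacent struts. A statistics layer provides
    the Wilcoxon signed-rank test, paired t-test, two-way consistency
    intraclass correlation and normality screening, plus an end-to-end
    experiment driver that emits tidy per-location measurements and summary
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    pracma,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
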