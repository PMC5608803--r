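Package: dcerrm
Title: Reference-Region Pharmacokinetic Analysis of DCE-MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative dynamic contrast-enhanced MRI (DCE-MRI) analysis
    without an arterial input function. Implements proton-density-referenced
    T1 mapping from spoiled gradient-echo (FLASH) signals, the linear
    reference-region model relating a tissue of interest to skeletal muscle
    with fixed literature kinetics, bounded least-squares identification of
    the transfer coefficient Ktrans and the extravascular extracellular
    volume fraction ve, Rayleigh-corrected signal-to-noise estimation, and
    longitudinal pairwise statistics with Bonferroni adjustment. Ships a
    synthetic phantom and cohort generator (Tofts kinetics, population
    arterial input functions, Rician noise) for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
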