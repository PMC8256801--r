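Package: trackRBE
Title: Track-Structure Microdosimetry and DNA Strand-Break RBE for
    Flattened and Flattening-Filter-Free Photon Fields
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes microdosimetric beam quality (dose-mean lineal
    energy) and initial DNA single- and double-strand-break yields from
    simplified electron track structure in liquid water, and derives the
    double-strand-break based relative biological effectiveness (RBE_DSB)
    of 6 MV flattened (FF) and flattening-filter-free (FFF) photon fields
    against a 220 kVp X-ray reference, at in-field and out-of-field
    positions in a water phantom. Secondary-electron spectra are emulated
    by a calibrated parametric family; tracks are generated by a compound
    cluster process; double-strand breaks are counted as event pairs
    within 3.4 nm (10 base pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
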