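Package: hptlcID
Title: Identification of Phenolic Compounds from HPTLC Band Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates bands on high-performance thin-layer chromatography
    (HPTLC) plates by matching their retention factors, colour hue angles and
    fluorescence/UV-Vis spectral summaries against a packaged reference
    library of 107 phenolic and related standards. Candidate identities are
    shortlisted with a cascade of inclusive tolerance filters (Rf +/-0.05,
    hue +/-60 degrees, wavelengths +/-15 nm before and +/-60 nm after
    derivatisation) and confirmed by overlaying normalised spectra, scored
    with Pearson correlation and a percent-within-band statistic, with
    rule-based selection among close candidates. Includes consolidation of
    matches across derivatisation reagents and mobile phases, and a
    synthetic-data generator for spectra and perturbed band observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
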