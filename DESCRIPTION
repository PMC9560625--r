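Package: zoomscreen
Title: ZooMS Collagen Peptide-Mass-Fingerprint Screening of Fragmented Bone Assemblages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for Zooarchaeology by Mass Spectrometry
    (ZooMS) screening of highly fragmented Palaeolithic bone assemblages:
    MALDI-ToF collagen peptide-mass-fingerprint processing (Savitzky-Golay
    smoothing, segmented baseline correction, signal-to-noise thresholded peak
    picking, deisotoping), marker-based taxonomic assignment with explicit
    ambiguity-group escalation rules, glutamine-deamidation (%Gln)
    quantification by two-component isotope-envelope deconvolution, and
    site-level zooarchaeological summarisation (NISP, %NISP with group-wise
    denominators, screening success rates). A synthetic-spectrum and
    synthetic-assemblage generator with known ground truth makes every stage
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    signal,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
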