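Package: xlpasef
Title: Ion-Mobility-Aware Cross-Linking Mass Spectrometry Workflow for
    DDA-PASEF Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Vendor-neutral workflow for analysing cross-linking mass
    spectrometry (XL-MS) experiments acquired with trapped ion mobility
    (DDA-PASEF). Merges ion-mobility-resolved fragment spectra into
    consensus MGF peak lists, computes precursor and fragment masses for
    DSBU (urea-based MS-cleavable) cross-linked peptide pairs including
    the diagnostic Bu/BuUr signature doublet, filters cross-link spectrum
    matches at a global target-decoy false discovery rate, builds
    precursor-specific inverse-reduced-mobility (1/K0) and indexed
    retention time (iRT) libraries, and performs peptide-centric
    validation of cross-links via extracted ion chromatograms across
    technical replicates and cross-linker-free negative controls. A
    seeded synthetic-study generator with full ground truth makes every
    stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
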