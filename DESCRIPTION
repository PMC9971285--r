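Package: oppkit
Title: Nascent-Proteome Mass Spectrometry with C-Terminal Puromycylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and quantification of nascent proteins labeled with
    O-propargyl-puromycin (OPP) and released through a cleavable biotin-azide
    linker. Implements monoisotopic mass arithmetic for the OPP/linker
    modification chemistry, MGF peak-list input/output with a diagnostic-ion
    (m/z 164.09) spectral filter, semi-specific peptide-spectrum matching with
    C-terminal variable modifications and target-decoy false discovery rate
    control, MS1 extracted-ion-chromatogram label-free quantification with
    protein rollup, the nascent-protein inclusion/exclusion filter with
    one-sample t-test volcano statistics, truncation-structure analyses with
    next-codon annotation of OPP incorporation sites, and a seeded synthetic
    data generator so that every pipeline stage is testable at desk scale.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    Biostrings,
    IRanges
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
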