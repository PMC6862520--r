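Package: dpcrscreen
Title: Chip-Based Digital PCR Screening for Fetal Aneuploidies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Analysis pipeline for duplex chip-based digital PCR (dPCR)
    screening of common fetal aneuploidies (trisomies 13, 18 and 21 and
    sex-chromosome aberrations). Implements Poisson absolute quantification
    of partition counts with Wilson confidence intervals, chromosomal dosage
    ratio estimation with delta-method intervals, threshold-based
    euploid/trisomy calling with mosaicism and maternal-contamination
    flagging, and an evaluation layer (Mann-Whitney group comparison, ROC
    with bootstrap confidence intervals, dilution-series regression and
    detection-limit estimation). A seeded synthetic chip simulator emulates
    ~20,000-well duplex chips, clinical cohorts and aneuploid/euploid
    dilution series for validation in the absence of deposited raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
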