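Package: p180curate
Title: Curation Pipeline for Targeted Metabolomics Plate Data with
    Medication Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Staged curation ("Level 0" through "Level 5") of targeted
    metabolomics concentrations exported from 96-well kit plates: per-plate
    technical validation against calibrator, kit-QC, blank and
    internal-standard acceptance rules; plate-specific limits of detection
    from zero-sample wells; cross-plate scaling anchored on a study pool QC;
    analyte filtering by duplicate coefficient of variation, intraclass
    correlation and censoring fraction; LOD/2 imputation; pre-analytical
    sample exclusion; principal-component outlier flagging; and conditional
    log2 transformation.  Also converts free-text medication records into a
    subject-by-drug-class Boolean matrix via normalization, approximate
    string matching against an offline lexicon, manual-review decisions,
    ingredient mapping and class rollup.  A seeded simulator generates
    plate exports, clinical tables and medication text with known ground
    truth so every stage is testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
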