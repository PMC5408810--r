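Package: methylite
Title: Single-Sample Preprocessing and Cross-Platform Integration of
    Infinium Methylation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing of Illumina Infinium BeadChip DNA methylation
    data with an emphasis on incremental, single-sample workflows.
    Implements normal-exponential background correction using out-of-band
    probes (Noob) with both reference-based and single-sample (ssNoob)
    dye-bias equalization, probe-level and CpG-locus-level combination of
    HumanMethylation450 and EPIC style datasets into virtual arrays,
    reference-based cell-type deconvolution by constrained projection with
    a cross-platform path, sample quality control and sex inference, and
    evaluation statistics for technical-replicate variance and
    distance-based classification. Includes a robust IDAT reader/writer
    with CSV fallback and a full synthetic-data generator used as the test
    bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    purrr,
    quadprog,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
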