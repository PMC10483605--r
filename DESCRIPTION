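Package: mvfcscreen
Title: Plasma-Only Tumor Mutation Screening and Residual Disease
    Detection from Variant Frequency Change
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies tumor-derived mutations in cell-free DNA using plasma
    alone, without matched tumor tissue, by comparing variant allele
    frequencies between pre- and post-operative plasma: the mutation variant
    frequency change (MVFC), the ratio of post- to pre-operative VAF.
    Mutations whose frequency collapses after surgery (MVFC < 0.2) are
    classified as tumor-derived; their post-operative persistence defines
    minimal residual disease (MRD), optionally combined with the serum
    markers AFP and DCP. Includes UMI-consensus-aware calling filters with
    PBMC-based removal of hematopoietic variants, MRD classification,
    survival and ROC evaluation statistics (Kaplan-Meier/log-rank, Cox
    regression, fixed-horizon and time-dependent AUC), and a synthetic
    cfDNA cohort simulator with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
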