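Package: mirunmask
Title: Pharmacologic Unmasking of Epigenetically Silenced miRNAs and
    Survival Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for genome-wide discovery of tumor-suppressive
    microRNAs silenced by DNA hypermethylation in multiple myeloma. Implements
    a demethylating-agent (5'azacytidine) upregulation screen over treated and
    control cell-line expression, tumor-versus-normal comparison of CpG
    methylation beta values near miRNA transcription start sites, consensus
    voting over miRNA target-prediction algorithms with intersection against
    tumor-upregulated genes, and a median-difference risk-score survival
    signature (RS = U - D) with equal-width risk levels and Cox
    proportional-hazards association. A synthetic-data module generates every
    input with known ground truth so all stages are testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
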