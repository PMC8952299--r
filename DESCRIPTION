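Package: apdtsig
Title: Query-Based APDT Response Signatures and Dormancy Phenotyping for
    Prostate Cancer Organoids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing androgen-pathway-directed-therapy (APDT)
    response in patient-derived prostate cancer organoids. Implements a
    query-based differential-expression procedure for heterogeneous organoid
    cultures: cross-experiment concordance filtering of fold changes between
    AR-agonist and AR-antagonist arms, inverse-variability ranking, and
    classification of responsive genes into four classes by direction and
    expression stratum. Includes RPKM quantification, expressed-gene
    filtering, GMT gene-set input/output, merged-category fold-enrichment
    scores with Fisher's 2x2 exact test, per-exon read-depth bias screening
    for truncated splice variants, Fucci2BL fluorescent cell-cycle state
    calling with dormancy and drug-washout reversibility statistics, and
    cyst/spheroid morphometry from labelled masks. A synthetic-data module
    generates every input type with planted ground truth so the full
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
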