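Package: methsub
Title: DNA Methylation Subtyping of Squamous Cell Carcinomas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative DNA-methylation subtyping pipeline for tumor
    cohorts profiled on Illumina 450k/27k beta-value arrays. Calls abnormal
    (hypo- or hypermethylated) gene states with beta-mixture models coupled
    to inverse methylation-expression association, discovers hypomethylated
    subtypes by consensus k-means clustering, classifies subtype membership
    within and across cohorts with a nearest-shrunken-centroid model under a
    confidence-abstention rule, and scores driver-gene lesions, germline
    hypomethylation-signature overlap, and T-cell expression signatures.
    Includes a synthetic cohort generator with planted subtypes and ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
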