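Package: pineGS
Title: Genomic and Pedigree Prediction with Nonadditive Effects for
    Forest Tree Breeding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Multi-kernel genomic evaluation for full-sib forest tree
    breeding populations. Builds pedigree-based additive and dominance
    relationship matrices and marker-based additive, dominance, and
    first-order epistatic kernels (Hadamard products), fits the
    corresponding PBLUP and GBLUP linear mixed models by average
    information REML, and derives narrow- and broad-sense
    heritabilities, cross-validated predictive ability and accuracy,
    selection response, and expected genetic gain under truncation
    selection. Includes a gene-drop simulator for partial diallel
    mating designs so the full pipeline can be exercised and validated
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
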