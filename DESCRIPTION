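Package: ctstab
Title: Reference Gene Stability Analysis for RT-qPCR
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selection and validation of RT-qPCR reference (housekeeping)
    genes from replicate-level Ct tables. Screens candidates from
    transcriptome RPKM ratios, performs Ct preprocessing and primer
    efficiency quality control, estimates expression stability with three
    algorithms (geNorm M-values with pairwise variation, model-based
    variance decomposition in the NormFinder style, and BestKeeper-style
    descriptive statistics with index correlation), aggregates the three
    rankings into a geometric-mean consensus, and validates reference
    choices by delta-delta-Ct relative quantification of a target gene.
    Includes a synthetic Ct data generator with known ground truth for
    testing every stage of the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
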