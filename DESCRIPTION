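Package: ribocn
Title: Ribosomal DNA Copy Number and Methylation from Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 47S ribosomal DNA (rDNA) copy number and CpG
    methylation from bisulfite-sequencing-derived inputs. Builds a
    "looped" (rotated) rDNA reference unit with pseudocopy masking and a
    filtered single-copy exome reference; estimates absolute copy number
    from whole-genome bisulfite (WGBS) depth ratios, relative copy number
    from reduced-representation (RRBS) read fractions, and copy number
    from droplet digital PCR concentrations; aggregates per-CpG
    methylation calls into region- and feature-level summaries with a
    coverage filter and methylation-adjusted ("active") copy numbers;
    applies per-sample sequencing QC; and provides the cohort association
    toolkit (rank tests with exact small-sample branches, age adjustment,
    twin-pair contrasts, exponential-plateau growth fits). A synthetic
    data generator with known ground truth makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    Rsamtools,
    GenomicAlignments,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
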