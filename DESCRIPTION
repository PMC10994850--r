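Package: bartag
Title: Design and Spike-Normalized Quantification of Chromosomal Barcode
    Tags for Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for tracking near-isogenic bacterial strains in synthetic
    communities with chromosomally integrated DNA barcode tags that are
    co-amplified with endogenous marker genes (bacterial 16S rRNA V5-V7,
    fungal ITS, plant ITS). Implements in-silico design of barcode tags by
    simulated random blunt-end ligation of 38-nt oligonucleotide units with
    size selection, assembly and validation of tag scaffolds carrying nested
    primer binding sites, assignment of amplicon reads to reference features
    by bounded edit distance, spike-in normalization of read counts,
    calibration and application of tag-to-16S amplification correction
    factors, standard-curve fitting over plasmid dilution series, and
    estimation of microbial load by cross-normalization against host ITS
    reads. A synthetic-data module generates communities, calibration sets,
    dilution series and error-bearing reads with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
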