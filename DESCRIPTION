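Package: ggnclone
Title: Subclonal CNV/LOH Deconstruction and Lineage Classification for
    Paired Tumor Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint inference of allele-specific copy number and loss of
    heterozygosity from binned read-depth log ratios and germline
    heterozygous SNP allele counts, using a hidden Markov model over
    genotype-state-by-subclone space with EM estimation of normal
    contamination and subclonal cellular prevalence. Includes a 3-state
    depth-only HMM segmenter for low-coverage data, genome-wide CNV
    correlation and cross-lesion subclone feature sharing for classifying
    paired synchronous lesions as parallel or independent lineages, and a
    synthetic paired-lesion generator with known clonal truth for testing
    the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    vcfR,
    rtracklayer,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
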