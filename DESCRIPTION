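Package: fhtwohit
Title: Two-Hit Variant Interpretation for FH-Deficient Tumors from Panel Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Interprets biallelic inactivation of the fumarate hydratase (FH)
    tumor suppressor from tumor-only targeted panel sequencing. Implements a
    tumor-purity/variant-allele-fraction model for germline versus somatic
    origin classification under loss of heterozygosity, purity-corrected
    conversion of log2 copy ratios to integer copy numbers, per-sample two-hit
    calling with an intratumoral-heterogeneity flag, saturation enumeration of
    coding single-nucleotide variants with protein-domain mapping, bootstrap
    spatial clustering of mutated residues on a protein structure, and
    carrier-frequency / prevalence arithmetic for pathogenic-variant
    epidemiology. A synthetic-cohort generator with known ground truth
    supports end-to-end validation of the whole chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    bio3d,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
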