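Package: rarecnv
Title: Rare Copy Number Variant Case-Control Analysis from SNP-Array Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a rare copy-number-variant (CNV)
    case-control pipeline for SNP-array data: hidden-Markov-model CNV
    segmentation from log R ratio (LRR) and B allele frequency (BAF) signal
    with GC-wave correction, dual-caller consensus and fragment merging,
    sample- and call-level quality filtering with rarity and artifact rules,
    per-sample CNV burden statistics with label-swapping permutation tests,
    and locus-level segmental and gene-based association testing with max(T)
    family-wise correction. Includes a synthetic cohort generator that
    simulates marker-level LRR/BAF intensities with embedded deletions and
    duplications, so the whole pipeline is testable without genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
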