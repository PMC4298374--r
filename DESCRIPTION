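Package: MultiRegionHet
Title: Intratumor Heterogeneity Analysis of Multi-Region Tumor Biopsies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for targeted sequencing of multiple spatially
    distinct biopsy cores from the same primary tumor. Filters per-biopsy
    somatic variant calls by variant allele fraction, depth, consequence
    class and germline-SNP membership; builds per-tumor binary mutation by
    region presence matrices and classifies mutations as shared (detected in
    every core) or nonshared; reconstructs clonal phylogenetic trees under a
    perfect-phylogeny model on binary characters; estimates pooled intratumor
    mutation prevalence per gene; and computes the binomial detection power
    of successive biopsies, including the minimum number of regions to
    sample for a target detection certainty. Includes a synthetic cohort
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), vcfR, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
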