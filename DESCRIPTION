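Package: scnaclone
Title: Clonal Inference from Single-Cell Whole-Genome Copy-Number Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing and clonal inference for single-cell whole-genome
    copy-number (CN) data from droplet-based scDNA-seq of tumors. Implements
    cell- and call-level quality filtering (DIMAPD Gaussian threshold, call
    quality, mappability), aggregation of 20 kb CN calls to mean-ploidy bins,
    maximum-likelihood clustering of CN profiles with AIC-based selection of k
    and recursive subclustering, discriminant analysis of principal components,
    synthesis and removal of doublet profiles and odd-copy-number artifact
    filtering, allele-specific CN with loss-of-heterozygosity and whole-genome
    doubling calls, mirrored allelic-imbalance detection, and CN-based
    phylogenies under balanced minimum evolution rooted at a diploid outgroup.
    A clone simulator generates datasets with full ground truth (multi-clone CN
    structure, WGD, haplotype-specific LOH, doublets, pseudodiploid, apoptotic
    and S-phase cells) so every stage is testable without controlled-access
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    withr
Config/testthat/edition: 3
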