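Package: karyotrace
Title: Haplotype-Aware Single-Cell Copy-Number Analysis and Karyotype
    History Reconstruction for Cleavage-Stage Embryos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to infer per-haplotype copy number in single blastomeres
    of hybrid-cross mouse embryos from binned read counts and SNP allelic
    depths, and to reconstruct the mitotic or meiotic origin of karyotype
    alterations across the first three cleavage divisions. Implements median
    normalization of binned coverage with low-coverage bin exclusion,
    replication-timing bias correction by local regression, circular binary
    segmentation, variant-allele-fraction based ploidy estimation with
    triploidy correction, detection of the half-copy underreplication
    signature of micronucleated chromosome fragments, structural-variant
    candidate filtering with joint genotyping across blastomeres, rule-based
    classification of segregation errors (reciprocal gain/loss, dicentric
    bridge monosomy, meiotic trisomy, digyny), quantification of DNA
    replication in micronuclei from two-channel EdU/DAPI images, and a
    synthetic embryo-lineage simulator with full ground truth for validating
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    tiff,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
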