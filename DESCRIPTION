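Package: haplodyn
Title: Haplotype-Resolved Expression Dynamics Under Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for haplotype-resolved transcriptome dynamics under salt
    (NaCl) and osmotic/drought (PEG) stress: FPKM quantification from
    fragment-count matrices, differential expression by a fixed-dispersion
    negative-binomial exact test with Benjamini-Hochberg correction,
    allele-specific expression (ASE) calling by a twofold allelic-ratio
    criterion, classification of per-gene bias trajectories across
    control/NaCl/PEG conditions into seven categories with salt/drought
    responsiveness accounting, a weighted co-expression network core
    (soft-threshold adjacency, topological overlap, module detection,
    eigengenes, module-trait correlation, hub screening), term enrichment by
    the hypergeometric test, set-intersection reporting, and a negative-
    binomial allele-level count simulator that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    edgeR,
    GenomicRanges,
    mclust,
    rtracklayer,
    S4Vectors,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
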