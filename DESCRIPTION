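Package: sticklescan
Title: Genome Scans of Divergence and Introgression for Diverging Species Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed genome-scan statistics and demographic inference for
    species pairs diverging with gene flow, built around a structured
    coalescent simulator. Computes Weir-Cockerham FST, absolute divergence
    (dXY), minimum-haplotype divergence (G_MIN), nucleotide diversity and
    Tajima's D in sliding windows; frequency-weighted four- and five-taxon
    site-pattern statistics (D, fd, partitioned D, D_FOIL) with introgression
    direction classification; hidden-Markov and permutation detection of
    introgression valleys and peaks with gene-overlap enrichment;
    ancestry-informative-marker hybrid indices; per-window neighbour-joining
    trees with topology classes and a genealogical sorting index;
    recombination-map interpolation; and hierarchical approximate Bayesian
    computation over isolation-with-migration models.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
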