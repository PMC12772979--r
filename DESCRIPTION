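Package: gsikit
Title: Genetic Stock Identification with GT-seq Microhaplotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and applying amplicon (GT-seq) panels for
    genetic stock identification of mixed-origin fishery samples. Provides
    synthetic baseline, mixture, read-count and FST-landscape generators under
    the Balding-Nichols model; Weir-Cockerham per-locus FST, exact and
    Monte-Carlo Hardy-Weinberg tests and a permutation linkage screen;
    an FST-ranked, windowed panel-selection algorithm; microhaplotype
    genotype calling with depth, depth-ratio, missingness and HWE filters;
    a Pella-Masuda conditional Bayesian mixture model (Gibbs sampler) with
    per-individual posteriors, z-score diagnostics, confidence filtering and
    leave-one-out simulated-mixture accuracy assessment; and Pearson
    chi-square tests of seasonal stock-composition change with Monte-Carlo
    p-values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    readr,
    withr,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
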