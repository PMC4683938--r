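Package: herdvar
Title: Population-Genetic Characterization of Diverging Livestock Populations
Version: 0.1.0
Authors@R:
    person("herdvar", "developers", email = "herdvar@example.org",
           role = c("aut", "cre"))
Description: SNP-chip population genetics for small diverging populations:
    genotype quality control, per-population diversity metrics, Weir-Cockerham
    F-statistics with locus bootstrap, Nei's standard genetic distance,
    LD-based effective population size (Burrows composite r2 with the Waples
    sample-size bias correction, per-chromosome batching), heterozygosity
    decay forecasting, rarefaction allelic richness and private allelic
    richness, VanRaden genomic relationships with principal components,
    one-level AMOVA with permutation significance, and allele-frequency
    population trees (Euclidean/Ward with marker bootstrap). Includes
    Balding-Nichols and forward Wright-Fisher simulators that provide ground
    truth for every estimator, plus a pipeline that writes table-shaped
    reports for any PED/MAP dataset.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
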