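Package: cherrydemog
Title: Microsatellite Diversity, Structure and Domestication Inference for Chinese Cherry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for diploid microsatellite data centred on the
    domestication genetics of Chinese cherry (Cerasus pseudocerasus): GenePop and
    tabular genotype input/output with missingness filtering; per-group diversity
    statistics (allelic richness by rarefaction, gene diversity, inbreeding
    coefficients, polymorphism information content) with permutation and
    Kruskal-Wallis tests; bottleneck detection by heterozygosity excess under a
    two-phase mutation model and by the Garza-Williamson M ratio; Bayesian
    admixture clustering with Evanno delta-K model choice, run alignment and
    threshold assignment; Nei's DA distances, neighbour-joining trees and
    principal coordinate analysis; directional relative migration networks with
    bootstrap significance; QST-FST comparison with Weir-Cockerham theta and an
    FST-outlier screen; and approximate Bayesian computation over four
    split-with-bottleneck demographic scenarios driven by a built-in structured
    coalescent simulator with generalized stepwise mutation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    MASS,
    nnet,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
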