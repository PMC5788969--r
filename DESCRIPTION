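Package: teapopgen
Title: Population-Genetic Analysis of Tea Domestication from Microsatellite
    and Chloroplast Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for studying the domestication history of the
    tea plant (Camellia sinensis) and its wild relatives from co-dominant
    nuclear microsatellite (nSSR) genotypes and maternally inherited
    chloroplast (cpDNA) sequences. Provides per-group diversity statistics
    (observed heterozygosity, Nei gene diversity, rarefied allelic richness,
    rare-allele percentage, inbreeding coefficient), a coalescent simulator
    of microsatellites under the strict stepwise mutation model for three
    competing demographic scenarios, approximate Bayesian computation (ABC)
    model choice with partial-least-squares summary-statistic reduction and
    regression adjustment, Bayesian genealogical-class assignment of hybrids
    (P1/P2/F1/F2/BC1/BC2) by Gibbs sampling, maximum-likelihood admixture
    clustering with Evanno delta-K model selection, and cpDNA haplotype
    collapsing with K2P distances, neighbor-joining trees and median-joining
    networks. A synthetic-data generator with the assumed lineage structure
    (three domesticated lineages plus a wild relative and hybrids of known
    class) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
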