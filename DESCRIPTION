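Package: paleomito
Title: Ancient Mitochondrial DNA Population Genetics with Serial-Sampling
    Coalescent Simulation and Approximate Bayesian Computation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genetic analysis of ancient mitochondrial
    HVS-I data: parsing of variant-motif shorthand and reconstruction of
    aligned sequence blocks, rule-tree assignment of mtDNA and Y-chromosome
    haplogroups from diagnostic variants, kinship-aware haplotype counting
    and haplogroup frequencies, pairwise PhiST and hierarchical AMOVA with
    permutation tests, metric multidimensional scaling and principal
    component analysis, temporal haplotype networks linking time-stratified
    sample layers, a serial-sampling structured coalescent simulator for
    haploid sequence data with divergence and pulse-admixture events, and an
    approximate Bayesian computation engine for demographic model choice and
    admixture-parameter estimation with a pseudo-observed validation suite.
    Ships the published Mogou (Di-Qiang, ~4000 yr BP) HVS-I haplotype table
    and Y-SNP panel as worked fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    igraph,
    nnet,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
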