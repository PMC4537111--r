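Package: guildsim
Title: Eco-Evolutionary Simulation of Foraging Guilds on Patchy Resource Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic agent-based simulation of foragers moving over a
    rectangular cellular array of renewing resource patches. Agents decide
    each tick whether to stay and extract resources or relocate within their
    Moore neighborhood, using a three-parameter (neighbor-discount,
    competition-tradeoff, movement-threshold) decision rule. Populations
    evolve by a genetic algorithm with an annealed mutation schedule under
    clonal, phenotype-averaging sexual, or diploid codominant random-mating
    reproduction. Includes post-hoc population-genetic analysis (allele
    frequencies, Hardy-Weinberg expected genotype counts and goodness of
    fit, morph classification) and a replicate-experiment driver comparing
    biomass production across reproduction modes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
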