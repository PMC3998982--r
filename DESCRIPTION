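Package: enaweb
Title: Ecological Network Analysis Indicators for Mass-Balanced Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for ecological network analysis of Ecopath-style
    mass-balanced food web models. Reads and validates static food web
    models (biomasses, production and consumption rates, diet matrix,
    fisheries removals), estimates ecotrophic efficiencies from the master
    balance equation, builds the extended flow network, and computes a
    standard suite of structural, functional and fishing indicators:
    throughput components, ascendency/overhead/redundancy information
    indices, Finn cycling, trophic levels, omnivory, Lindeman-spine
    transfer efficiencies, primary production required to sustain catches,
    the loss-in-production index, mixed trophic impacts and
    keystoneness/dominance key-role indices. Collection-level statistics
    (distance-based permutational ANOVA with covariates, chi-square
    decomposition and correspondence analysis of key-role by trait
    tables) and a seeded generator of balanced synthetic food webs allow
    the whole pipeline to be exercised without external model databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml
Config/testthat/edition: 3
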