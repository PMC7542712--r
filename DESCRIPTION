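Package: copolphase
Title: Subgenome Assignment in Allopolyploids by Minimizing Deep Coalescences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns alleles sampled from a polyploid taxon to hypothetical
    diploid subgenomes by minimizing the number of deep coalescences (extra
    lineages) across multi-locus gene trees. Optimization over constrained
    allele partitions uses a tabu-search metaheuristic scored by an internal
    minimizing-deep-coalescences (MDC) species-tree engine. Replicate
    reconstructions are combined by an entropy-minimizing alignment of
    subgenome labels followed by greedy consensus. A multispecies-coalescent
    simulator (Yule species trees, coalescent gene trees, artificial
    allopolyploids) supports validation via normalized Robinson-Foulds
    distances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
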