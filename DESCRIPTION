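Package: phytraits
Title: Phylogenetic Signal, Correlated Evolution and Biogeographic Events
    for Binary Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative-phylogenetics toolkit for binary characters on dated
    phylogenies. Computes the Fritz-Purvis D statistic for phylogenetic signal
    with permutation and Brownian-threshold simulated nulls, summarised over
    posterior tree samples; counts trait gains and losses by multifurcating
    Fitch parsimony with min/max ranges over most-parsimonious reconstructions;
    tests correlated evolution of two binary traits with phylogenetically
    independent pairwise comparisons and a sign test; classifies and time-bins
    dispersal, extinction, vicariance and peripheral-isolation events from
    ancestral-range reconstructions; performs simple indel coding of alignment
    gaps and multi-locus concatenation. A synthetic-data module simulates
    pure-birth trees, binary traits under shuffle, Brownian-threshold, Mk and
    correlated-pair models, and forward range histories with ground-truth
    event logs, so the whole analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
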