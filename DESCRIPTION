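Package: recombsim
Title: Forward-in-Time Simulation of Prokaryotic Genome Evolution with
    Homologous Recombination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tree-guided forward-in-time simulation of core and accessory
    genome evolution for prokaryotes. A root genome is evolved along a rooted
    phylogeny under JC69, K2P, K3P or GTR nucleotide substitution with
    codon-position rate heterogeneity; homologous recombination (gene
    conversion) is restricted to lineages co-existing in the same time segment
    of the tree, with geometric tract lengths, optional log-linear
    divergence-dependent acceptance, and whole-gene transfer or deletion rules
    at core/accessory boundaries. Gene gain (external horizontal transfer) and
    gene loss produce accessory genomes. The simulator reports the statistic
    eta and the effective recombination rate r/m together with event logs and
    parameter-recovery summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
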