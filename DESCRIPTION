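Package: panphylo
Title: Phylogenetic Analysis of Trait Gain, Loss and Exchange in Microbial Pangenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how a discrete metabolic trait (such as
    nitrate assimilation in Prochlorococcus) is gained, lost and exchanged
    across a microbial radiation. Implements weighted (Sankoff) parsimony and
    Mk-model maximum-likelihood ancestral state reconstruction with
    likelihood-ratio comparison of symmetric and asymmetric rate models;
    recovery-corrected core/flexible gene classification, Jaccard
    average-linkage clustering and hypergeometric marker enrichment for
    partial single-cell genome assemblies; unweighted UniFrac and parsimony
    P-test permutation tests of population divergence; Goldman-Yang codon
    site and branch-site models of selection with likelihood-ratio tests;
    ClonalFrame-style recombination summary statistics (rho/theta, r/m) and a
    forward simulator of homologous recombination; and the membrane transport
    free-energy calculation used in macroevolutionary arguments about
    nutrient acquisition. A synthetic-data generator produces trees, traits,
    partial genomes, recombinant alignments and codon alignments so the whole
    pipeline can be exercised without external genome data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
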