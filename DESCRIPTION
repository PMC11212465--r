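Package: symcord
Title: Phylogenomic Incongruence and Floral Symmetry Evolution at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested, reusable pipeline for target-capture phylogenomics of
    the kind used to study cyto-nuclear discordance and floral symmetry
    evolution in Ranunculales. Provides coalescent simulation of gene trees
    within a species tree (with optional post-hybridization introgression and
    a plastid c-gene), sequence simulation, recovery quality control with a
    coverage score (representedness, completeness, evenness) and paralog and
    median-score gene filters, alignment statistics and trimming, maximum
    likelihood gene trees with bootstrap and bipartition collapsing,
    quartet-based species tree estimation under the multispecies coalescent
    with local posterior probabilities and coalescent-unit branch lengths,
    concatenated partitioned maximum likelihood with gene-and-site bootstrap,
    penalized-likelihood divergence dating with fossil calibrations and
    cross-validation, equal-rates Mk ancestral state reconstruction, and
    tanglegram-style discordance quantification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape (>= 5.0),
    phangorn,
    phytools,
    stats,
    utils,
    jsonlite,
    yaml,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
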