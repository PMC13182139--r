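Package: quartetpol
Title: Polarized Quartet Support, Homoplasy Filtering and Rooted
    Clade-Supertree Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies phylogenetic signal for alternative rooted
    relationships among predefined clades by scoring polarized
    species-quartets (three ingroup taxa plus an outgroup) drawn from a
    concatenated alignment.  For every quartet the synapomorphic site
    count supporting each of the three rooted topologies is contrasted
    with the convergent site count expected under a GTR+Gamma+I model
    fitted to the quartet subalignment; weak or convergence-dominated
    quartets are removed by automatically optimized support-distance
    (DIST) and homoplasy-ratio (RISK) filters; retained support is
    aggregated to clade-quartet medians and all rooted binary clade
    trees are ranked exhaustively by summed compatible-quartet support.
    Includes a multispecies-coalescent simulator of supermatrices with
    gene-tree discordance and branch-rate heterogeneity for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Rcpp,
    seqinr,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
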