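Package: divdim
Title: Diversity Metrics and Their Dimensionality in Grassland Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Plot-level taxonomic (Gini-Simpson), phylogenetic (Rao
    quadratic entropy on divergence times, averaged over random graftings
    of species missing from the phylogeny) and functional (Rao entropy on
    Gower trait distances) diversity for vegetation surveys under
    contrasting land use; community-weighted mean traits; permutation null
    models with standardized effect sizes; Blomberg's K phylogenetic
    signal; Kruskal-Wallis and pairwise Wilcoxon comparisons with compact
    letter displays; and the dimensionality of biodiversity through
    eigenvalue evenness and metric importance values with bootstrap
    confidence intervals. Includes a synthetic-study generator (Yule
    trees, Brownian-motion traits, neutral, filtering and
    limiting-similarity community assembly) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    phytools,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    vegan
Config/testthat/edition: 3
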