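Package: phet
Title: Soil Nutrient Heterogeneity, Tree Diversity and Community
    Phylogenetic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking within-plot soil nutrient
    heterogeneity (coefficient of variation of replicate samples) to tree
    species diversity and community phylogenetic structure. Computes
    per-plot richness, Shannon diversity and effective number of species,
    individual-based analytic rarefaction, mean pairwise phylogenetic
    distance (MPD) with standardized effect sizes under a taxa-labels
    permutation null (net relatedness index, NRI), rooted Faith
    phylogenetic diversity with analytic individual-based rarefaction,
    Hill-number phylogenetic diversity of order q = 1, and a Pearson
    correlation layer with Shapiro-Wilk normality screening. Includes a
    synthetic-data generator producing communities, ultrametric
    phylogenies and replicated soil samples under niche-coupled, unimodal
    and neutral assembly scenarios so every stage of the pipeline can be
    exercised and calibrated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
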