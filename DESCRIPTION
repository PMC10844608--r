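Package: floraphylo
Title: Phylogenetic Structure of Regional Floras and Its Environmental Drivers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes phylogenetic-structure metrics of regional species
    assemblages (Faith's PD with area correction, mean pairwise distance,
    relative phylogenetic diversity, and standardized effect sizes of PD and
    MPD under a uniform tip-sampling null), relates them to current-climate,
    historical-climate-change, and environmental-heterogeneity variables with
    maximum-likelihood simultaneous autoregressive (SAR) error models, and
    partitions explained variation among variable sets using adjusted R
    squared. Includes a seeded synthetic-world generator (birth-death
    phylogeny, Brownian niche evolution, spatially autocorrelated
    environmental surfaces, niche-filtered assemblages) so the full pipeline
    can be exercised and validated without the global flora and climate
    datasets it is designed for.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    ape,
    phytools,
    geosphere,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    vegan,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
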