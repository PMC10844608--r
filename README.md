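# floraphylo

Phylogenetic structure of regional floras and its environmental drivers.

Regional species assemblages carry a phylogenetic signature of how they
were put together. Floras of cold regions tend to be drawn from a few
young, cold-adapted radiations (phylogenetic clustering), while warm-region
floras sample the species pool much more evenly — the footprint of tropical
niche conservatism. `floraphylo` quantifies this structure, relates it to
the environment with spatial regression, and partitions the explained
variation among competing groups of drivers:

* **Metrics** — Faith's PD (with area correction), mean pairwise distance
  (MPD), relative phylogenetic diversity (RPD), and standardized effect
  sizes of PD and MPD under a uniform species-pool null (Monte Carlo or
  exhaustive enumeration).
* **Spatial statistics** — great-circle k-nearest-neighbour spatial
  weights, Moran's I, and a maximum-likelihood simultaneous autoregressive
  (SAR) error model with standardized coefficients.
* **Variation partitioning** — two- and three-set partitions on adjusted
  R² among current climate (C), historical climate change (H), and
  environmental heterogeneity (V), plus subgroup designs.
* **Synthetic worlds** — a fully seeded generator (birth–death phylogeny
  at fixed crown age, Brownian niche evolution with derived cold-adapted
  clades, spatially autocorrelated environmental surfaces, deterministic
  niche-filtered assembly), so every result is reproducible bit for bit
  and the known generative truth validates the pipeline end to end.
* **Pipeline** — `run_all()` chains everything: metric table, SAR
  coefficients per scope (global and per continent), the partition suite,
  and figure-style summaries.

See the vignette
(`vignettes/phylogenetic-structure-of-regional-floras.Rmd`) for the
methods and the generator's design rationale.

## Worked example

```r
library(floraphylo)

config <- synthetic_config(seed = 42, grid_nx = 8, grid_ny = 8, n_subcells = 9)
world <- simulate_world(config)
metrics <- compute_metric_table(world$tree, world$assemblages, world$regions,
                                null_spec(499, seed = 43))
head(metrics, 4)
#>   region_id richness    PD    MPD    RPD PD_ses MPD_ses
#> 1      r001       54 131.9  97.87 0.8969 -13.35 -12.694
#> 2      r002       55 122.3 101.32 0.8951 -12.34 -11.939
#> 3      r003       55 122.1 101.32 0.8951 -12.60 -11.590
#> 4      r004       62 134.7 118.90 0.9049 -12.87  -7.821
```

Relate clustering to minimum temperature with a spatial error model on
z-scored variables:

```r
d <- merge(metrics, world$env, by = "region_id")
d <- d[is.finite(d$MPD_ses), ]
W <- build_weights(world$regions[match(d$region_id, world$regions$region_id), ],
                   k = 8)
fit <- standardized_sar(d$MPD_ses, d$T_min, W)
fit$std_coef
#> [1] 0.864
```

The strongly positive coefficient is the niche-conservatism signature:
floras become more clustered (more negative `MPD_ses`) the colder the
region. Partition the variation among driver groups:

```r
grp <- variable_groups()
varpart3(d$MPD_ses, grp$C, grp$H, grp$V, d, names = c("C", "H", "V"))
#> three_set variation partition (groups: C, H, V )
#>     pure_C     pure_H     pure_V  shared_CH  shared_CV  shared_HV shared_CHV
#>     0.3365     0.0408     0.0008     0.3867     0.0450    -0.0045     0.0119
#>   residual
#>     0.1828
```

Current climate dominates: its pure fraction (0.34) dwarfs the pure
fractions of climate history (0.04) and heterogeneity (0.001).

## Testing

```r
testthat::test_dir("tests/testthat")
```

The suite validates the metrics against brute-force enumeration over all
tip subsets, the SES nulls against exhaustive enumeration, the SAR model
against simulations with known parameters (including its nominal type-I
error), the partitions against independent inclusion–exclusion oracles
(and `vegan::varpart`), and the end-to-end pipeline for determinism and
the emergence of the niche-conservatism signature across many simulated
worlds.
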