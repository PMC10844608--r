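# Shared settings for the analysis drivers. Every driver sources this file,
# so the whole workflow is controlled from one place. Paths are relative to
# the repository root; run the drivers from there, e.g.
#   Rscript analysis/01_simulate.R

library(floraphylo)

results_dir <- "results"
world_dir <- file.path(results_dir, "world")
dir.create(results_dir, showWarnings = FALSE, recursive = TRUE)

# The study configuration: one synthetic world with the package defaults
# (the defaults encode the study regime; see the vignette for the rationale).
config <- synthetic_config(seed = 20240101)

# Monte Carlo randomizations for the standardized-effect-size nulls, and
# spatial-model settings shared by every driver.
n_randomizations <- 999
k_neighbours <- 8
min_regions <- 16
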