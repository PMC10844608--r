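# Compute the five phylogenetic-structure metrics (PD, MPD, RPD, PD_ses,
# MPD_ses) for every regional flora of the simulated world.

source("analysis/00_config.R")

world <- read_world(world_dir)
null <- null_spec(n_randomizations = n_randomizations, seed = config$seed + 1L)

metrics <- compute_metric_table(world$tree, world$assemblages, world$regions,
                                null)
write_metric_table(metrics, file.path(results_dir, "metrics.tsv"))

print(summary(metrics[, c("richness", "PD", "MPD", "RPD", "PD_ses",
                          "MPD_ses")]))
cat("metric table written to", file.path(results_dir, "metrics.tsv"), "\n")
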