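# Simulate the synthetic world (phylogeny, niches, regions, environmental
# surfaces, assemblages) and write it to results/world/.

source("analysis/00_config.R")

world <- simulate_world(config)
write_world(world, world_dir)

cat("tips:", length(world$tree$tip.label),
    " regions:", nrow(world$regions),
    " occupancy rows:", nrow(world$assemblages), "\n")
cat("world written to", world_dir, "\n")
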