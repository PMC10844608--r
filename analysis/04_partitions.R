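# Partition, for every scope and metric, the variation of the metric among
# current climate (C), climate-change/historical (H) and environmental
# heterogeneity (V) variable groups, plus the temperature/precipitation and
# elevation/subcell-climate subgroup designs.

source("analysis/00_config.R")

world <- read_world(world_dir)
metrics <- readr::read_tsv(file.path(results_dir, "metrics.tsv"),
                           show_col_types = FALSE)

scopes <- make_scopes(world$regions, min_n = min_regions)
parts <- run_partition_suite(metrics, world$env, world$regions, scopes,
                             min_n = min_regions, k = k_neighbours)
readr::write_tsv(parts, file.path(results_dir, "partitions.tsv"))

cat("rows:", nrow(parts), "\n")
cat("partition table written to",
    file.path(results_dir, "partitions.tsv"), "\n")
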