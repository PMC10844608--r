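# Fit, for every scope (global + continents), metric and environmental
# variable, a simultaneous autoregressive error model on z-scored variables
# and record the standardized coefficient.

source("analysis/00_config.R")

world <- read_world(world_dir)
metrics <- readr::read_tsv(file.path(results_dir, "metrics.tsv"),
                           show_col_types = FALSE)

scopes <- make_scopes(world$regions, min_n = min_regions)
coefs <- run_coefficients(metrics, world$env, world$regions, scopes,
                          k = k_neighbours, min_n = min_regions)
readr::write_tsv(coefs, file.path(results_dir, "coefficients.tsv"))

cat("rows:", nrow(coefs), " scopes:",
    paste(unique(coefs$scope), collapse = ", "), "\n")
cat("coefficient table written to",
    file.path(results_dir, "coefficients.tsv"), "\n")
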