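# Aggregate the coefficient and partition tables: mean absolute coefficient
# per variable, continental-mean coefficients, and mean fractions by scope
# and by metric.

source("analysis/00_config.R")

coefs <- readr::read_tsv(file.path(results_dir, "coefficients.tsv"),
                         show_col_types = FALSE)
parts <- readr::read_tsv(file.path(results_dir, "partitions.tsv"),
                         show_col_types = FALSE)

summ <- summarize_results(coefs, parts)
readr::write_tsv(summ$coef_by_variable,
                 file.path(results_dir, "summary_coef_by_variable.tsv"))
readr::write_tsv(summ$continental_mean_coef,
                 file.path(results_dir, "summary_continental_mean_coef.tsv"))
readr::write_tsv(summ$part_by_scope,
                 file.path(results_dir, "summary_part_by_scope.tsv"))
readr::write_tsv(summ$part_by_metric,
                 file.path(results_dir, "summary_part_by_metric.tsv"))

top <- dplyr::arrange(
  summ$coef_by_variable[summ$coef_by_variable$scope == "global", ],
  dplyr::desc(mean_abs_coef))
cat("strongest global predictors (mean |standardized coefficient|):\n")
print(utils::head(as.data.frame(top), 5))
cat("summaries written to", results_dir, "\n")
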