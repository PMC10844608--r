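#' Define analysis scopes: global plus one per continent
#'
#' Continent membership comes from the region table, never re-derived from
#' coordinates. Scopes with too few regions are skipped with a warning.
#'
#' @param regions Region table with `region_id` and `continent`.
#' @param min_n Minimum regions per scope (a scope needs `n > min_n`).
#' @return Named list of scopes, each a list with `label` and `region_ids`.
#' @export
make_scopes <- function(regions, min_n = 16) {
  scopes <- list(list(label = "global",
                      region_ids = as.character(regions$region_id)))
  for (cont in sort(unique(regions$continent))) {
    ids <- as.character(regions$region_id[regions$continent == cont])
    if (length(ids) <= min_n) {
      warning("scope continent:", cont, " has only ", length(ids),
              " regions (minimum ", min_n + 1, "); skipped", call. = FALSE)
      next
    }
    scopes <- c(scopes, list(list(label = paste0("continent:", cont),
                                  region_ids = ids)))
  }
  names(scopes) <- vapply(scopes, `[[`, character(1), "label")
  scopes
}

.metric_names <- c("PD", "MPD", "RPD", "PD_ses", "MPD_ses")

#' Per-variable standardized SAR coefficients for every metric and scope
#'
#' For each scope, each of the five phylogenetic metrics is regressed on each
#' of the 13 environmental variables with a SAR error model on z-scored
#' variables. Regions with a missing metric value are dropped pairwise per
#' (metric, scope), and the spatial weights are rebuilt from the centroids of
#' the retained regions of that scope.
#'
#' @param metric_table Output of [compute_metric_table()].
#' @param env Environment table (`region_id` + 13 variables).
#' @param regions Region table with centroids and continents.
#' @param scopes Output of [make_scopes()]; default derives from `regions`.
#' @param k Neighbours for the spatial weights (default 8).
#' @param min_n Minimum usable regions per (metric, scope).
#' @return Tibble: `metric`, `variable`, `scope`, `std_coef`, `lambda`,
#'   `pseudo_r2`, `n` (65 rows per scope; `NA` coefficients where a metric
#'   is constant or too sparse within a scope).
#' @export
run_coefficients <- function(metric_table, env, regions, scopes = NULL,
                             k = 8, min_n = 16) {
  if (is.null(scopes)) scopes <- make_scopes(regions, min_n)
  vars <- unlist(variable_groups()[c("C", "H", "V")], use.names = FALSE)
  regions <- as.data.frame(regions)
  out <- list()
  for (sc in scopes) {
    dat <- dplyr::inner_join(
      metric_table[metric_table$region_id %in% sc$region_ids, ],
      env, by = "region_id")
    for (m in .metric_names) {
      keep <- is.finite(dat[[m]])
      sub <- dat[keep, ]
      usable <- nrow(sub) > min_n && stats::sd(sub[[m]]) > 0
      if (usable) {
        cent <- regions[match(sub$region_id, regions$region_id), ]
        W <- build_weights(cent, k = k)
        ev <- eigen(W$W, only.values = TRUE)$values
        rows <- lapply(vars, function(v) {
          r <- standardized_sar(sub[[m]], sub[[v]], W, ev = ev)
          tibble::tibble(metric = m, variable = v, scope = sc$label,
                         std_coef = r$std_coef, lambda = r$fit$lambda,
                         pseudo_r2 = r$fit$pseudo_r2, n = nrow(sub))
        })
      } else {
        rows <- lapply(vars, function(v) {
          tibble::tibble(metric = m, variable = v, scope = sc$label,
                         std_coef = NA_real_, lambda = NA_real_,
                         pseudo_r2 = NA_real_, n = nrow(sub))
        })
      }
      out <- c(out, rows)
    }
  }
  dplyr::bind_rows(out)
}

.partition_designs <- function() {
  list(
    C_H   = list(type = "two", sets = c("C", "H")),
    C_V   = list(type = "two", sets = c("C", "V")),
    H_V   = list(type = "two", sets = c("H", "V")),
    C_H_V = list(type = "three", sets = c("C", "H", "V")),
    T_P   = list(type = "two", sets = c("T", "P")),
    E_S   = list(type = "two", sets = c("E", "S"))
  )
}

#' Variation-partitioning suite for every metric and scope
#'
#' Runs, per scope and metric, the three pairwise designs among the major
#' variable groups (C|H, C|V, H|V), the three-set design (C,H,V), and the
#' two current-climate subgroup designs (T|P, E|S), on adjusted R-squared
#' from OLS fits (default).
#'
#' @inheritParams run_coefficients
#' @param r2_source `"ols"` (default) or `"sar_trend"`.
#' @return Long tibble: `metric`, `scope`, `design`, `fraction_label`,
#'   `value`, `n`.
#' @export
run_partition_suite <- function(metric_table, env, regions, scopes = NULL,
                                r2_source = "ols", min_n = 16, k = 8) {
  if (is.null(scopes)) scopes <- make_scopes(regions, min_n)
  grp <- variable_groups()
  designs <- .partition_designs()
  regions <- as.data.frame(regions)
  out <- list()
  for (sc in scopes) {
    dat <- dplyr::inner_join(
      metric_table[metric_table$region_id %in% sc$region_ids, ],
      env, by = "region_id")
    for (m in .metric_names) {
      sub <- dat[is.finite(dat[[m]]), ]
      if (nrow(sub) <= min_n || stats::sd(sub[[m]]) == 0) next
      W <- if (r2_source == "sar_trend") {
        build_weights(regions[match(sub$region_id, regions$region_id), ], k = k)
      } else NULL
      y <- sub[[m]]
      for (dn in names(designs)) {
        d <- designs[[dn]]
        p_union <- length(unique(unlist(grp[d$sets])))
        if (nrow(sub) < p_union + 2) {
          warning("scope ", sc$label, ", metric ", m, ": n = ", nrow(sub),
                  " too small for design ", dn, "; skipped", call. = FALSE)
          next
        }
        pr <- if (d$type == "two") {
          varpart2(y, grp[[d$sets[1]]], grp[[d$sets[2]]], sub,
                   names = d$sets, r2_source = r2_source, W = W)
        } else {
          varpart3(y, grp[[d$sets[1]]], grp[[d$sets[2]]], grp[[d$sets[3]]],
                   sub, names = d$sets, r2_source = r2_source, W = W)
        }
        vals <- c(pr$fractions, residual = pr$residual)
        out <- c(out, list(tibble::tibble(
          metric = m, scope = sc$label, design = dn,
          fraction_label = names(vals), value = unname(vals), n = nrow(sub))))
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize coefficient and partition tables the way the figures do
#'
#' Produces (a) the mean absolute standardized coefficient per variable
#' across the five metrics, per scope; (b) the continental-mean coefficient
#' per (metric, variable), averaging the per-continent models; (c) fraction
#' values averaged across metrics per scope and design; (d) fraction values
#' averaged across continents per metric and design. Missing cells are
#' excluded, with the contributing count reported.
#'
#' @param coef_table Output of [run_coefficients()].
#' @param part_table Output of [run_partition_suite()].
#' @return List of tibbles: `coef_by_variable`, `continental_mean_coef`,
#'   `part_by_scope`, `part_by_metric`.
#' @export
summarize_results <- function(coef_table, part_table) {
  coef_by_variable <- coef_table |>
    dplyr::group_by(.data$scope, .data$variable) |>
    dplyr::summarise(
      mean_abs_coef = mean(abs(.data$std_coef), na.rm = TRUE),
      n_metrics = sum(is.finite(.data$std_coef)), .groups = "drop")

  continental_mean_coef <- coef_table |>
    dplyr::filter(startsWith(.data$scope, "continent:")) |>
    dplyr::group_by(.data$metric, .data$variable) |>
    dplyr::summarise(
      mean_coef = mean(.data$std_coef, na.rm = TRUE),
      n_continents = sum(is.finite(.data$std_coef)), .groups = "drop")

  part_by_scope <- part_table |>
    dplyr::group_by(.data$scope, .data$design, .data$fraction_label) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE),
                     n_metrics = sum(is.finite(.data$value)), .groups = "drop")

  part_by_metric <- part_table |>
    dplyr::filter(startsWith(.data$scope, "continent:")) |>
    dplyr::group_by(.data$metric, .data$design, .data$fraction_label) |>
    dplyr::summarise(mean_value = mean(.data$value, na.rm = TRUE),
                     n_continents = sum(is.finite(.data$value)), .groups = "drop")

  list(coef_by_variable = coef_by_variable,
       continental_mean_coef = continental_mean_coef,
       part_by_scope = part_by_scope,
       part_by_metric = part_by_metric)
}

#' Run the complete analysis end to end on a synthetic world
#'
#' Simulates the world from the configuration, computes the metric table,
#' the SAR coefficient table, the partition suite, and the summaries, and
#' (optionally) writes every table plus a run manifest with a configuration
#' hash. Bit-reproducible given the configuration (which carries the seed).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory; when given, all tables are
#'   written as TSV with fixed column orders.
#' @param n_randomizations Monte Carlo draws for the SES null (default 499).
#' @param k Spatial-weights neighbours (default 8).
#' @param min_n Minimum regions per scope.
#' @return List: `world`, `metrics`, `coefficients`, `partitions`,
#'   `summary`.
#' @export
run_all <- function(config = synthetic_config(), out_dir = NULL,
                    n_randomizations = 499, k = 8, min_n = 16) {
  world <- simulate_world(config)
  null <- null_spec(n_randomizations = n_randomizations,
                    seed = config$seed + 1L)
  metrics <- compute_metric_table(world$tree, world$assemblages,
                                  world$regions, null)
  scopes <- make_scopes(world$regions, min_n)
  coefs <- run_coefficients(metrics, world$env, world$regions, scopes, k = k,
                            min_n = min_n)
  parts <- run_partition_suite(metrics, world$env, world$regions, scopes,
                               min_n = min_n, k = k)
  summ <- summarize_results(coefs, parts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_world(world, file.path(out_dir, "world"))
    write_metric_table(metrics, file.path(out_dir, "metrics.tsv"))
    readr::write_tsv(coefs, file.path(out_dir, "coefficients.tsv"))
    readr::write_tsv(parts, file.path(out_dir, "partitions.tsv"))
    readr::write_tsv(summ$coef_by_variable,
                     file.path(out_dir, "summary_coef_by_variable.tsv"))
    readr::write_tsv(summ$continental_mean_coef,
                     file.path(out_dir, "summary_continental_mean_coef.tsv"))
    readr::write_tsv(summ$part_by_scope,
                     file.path(out_dir, "summary_part_by_scope.tsv"))
    readr::write_tsv(summ$part_by_metric,
                     file.path(out_dir, "summary_part_by_metric.tsv"))
    cfg <- world$config; class(cfg) <- NULL
    manifest <- list(config = cfg, config_hash = rlang::hash(cfg),
                     n_randomizations = n_randomizations, k = k, min_n = min_n)
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(world = world, metrics = metrics, coefficients = coefs,
       partitions = parts, summary = summ)
}

#' Read the delimited inputs the pipeline consumes
#'
#' @param dir Directory containing `tree.nwk`, `assemblages.tsv`,
#'   `regions.tsv`, `environment.tsv` (as written by [write_world()]).
#' @return List: `tree`, `assemblages`, `regions`, `env`.
#' @export
read_world <- function(dir) {
  list(
    tree = validate_phylo(ape::read.tree(file.path(dir, "tree.nwk"))),
    assemblages = readr::read_tsv(file.path(dir, "assemblages.tsv"),
                                  show_col_types = FALSE),
    regions = readr::read_tsv(file.path(dir, "regions.tsv"),
                              show_col_types = FALSE),
    env = readr::read_tsv(file.path(dir, "environment.tsv"),
                          show_col_types = FALSE)
  )
}
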