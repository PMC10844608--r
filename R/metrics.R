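#' Faith's phylogenetic diversity of a tip set
#'
#' Sum of branch lengths on the union of root-to-tip paths of the sampled
#' tips (root-inclusive), so PD of a single tip equals its root distance and
#' PD of the full tip set equals the total tree length.
#'
#' @param tree A `phylo` object with edge lengths.
#' @param tips Character vector of tip labels (non-empty).
#' @return A single non-negative number.
#' @export
faith_pd <- function(tree, tips) {
  idx <- .tip_indices(tree, tips)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ape::Ntip(tree) + tree$Nnode
  has_sampled <- logical(nn)
  has_sampled[idx] <- TRUE
  parent <- po$edge[, 1]
  child <- po$edge[, 2]
  for (e in seq_along(parent)) {
    if (has_sampled[child[e]]) has_sampled[parent[e]] <- TRUE
  }
  sum(po$edge.length[has_sampled[child]])
}

.tip_indices <- function(tree, tips) {
  if (length(tips) == 0L) stop("tip set must be non-empty", call. = FALSE)
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) {
    stop("unknown tip label(s): ", paste(tips[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  idx
}

# Edge-by-tip descendant indicator matrix: entry (e, t) is 1 when tip t
# descends from edge e. Used to vectorise PD over many sampled sets.
edge_tip_matrix <- function(tree) {
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  desc <- matrix(0, nrow = nn, ncol = ntip)
  desc[cbind(seq_len(ntip), seq_len(ntip))] <- 1
  parent <- po$edge[, 1]
  child <- po$edge[, 2]
  for (e in seq_along(parent)) {
    desc[parent[e], ] <- desc[parent[e], ] + desc[child[e], ]
  }
  M <- (desc[child, , drop = FALSE] > 0) * 1
  rownames(M) <- NULL
  list(M = M, edge_length = po$edge.length)
}

#' Area-corrected phylogenetic diversity
#'
#' Divides PD by the base-10 logarithm of region area in square kilometres,
#' accounting for the species-area driven increase of PD with region size.
#'
#' @param pd PD value(s).
#' @param area Region area(s) in km^2; must exceed 1 km^2 (log10 > 0), and a
#'   warning is issued for areas of 10 km^2 or less (log10 <= 1).
#' @return `pd / log10(area)`, vectorised.
#' @export
area_corrected_pd <- function(pd, area) {
  if (any(area <= 1)) {
    stop("area must exceed 1 km^2 (log10(area) would be <= 0)", call. = FALSE)
  }
  if (any(area <= 10)) {
    warning("area <= 10 km^2: log10(area) <= 1 inflates area-corrected PD",
            call. = FALSE)
  }
  pd / log10(area)
}

#' Mean pairwise patristic distance of a tip set
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of at least two tip labels.
#' @param dist Optional precomputed patristic matrix (from
#'   [patristic_matrix()]) to avoid repeated cophenetic computation.
#' @return Unweighted mean over all unordered tip pairs.
#' @export
mpd <- function(tree, tips, dist = NULL) {
  idx <- .tip_indices(tree, tips)
  if (length(idx) < 2L) stop("MPD requires at least 2 tips", call. = FALSE)
  if (is.null(dist)) dist <- patristic_matrix(tree)
  sub <- dist[tree$tip.label[idx], tree$tip.label[idx]]
  mean(sub[upper.tri(sub)])
}

#' Relative phylogenetic diversity of a tip set
#'
#' PD of the tip set on the observed tree divided by PD on a comparison tree
#' of identical topology whose branch lengths are all equal, each PD first
#' expressed as a fraction of its tree's total length. Values above 1 indicate
#' over-representation of long branches in the assemblage.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of tip labels (non-empty).
#' @return A positive ratio; exactly 1 for the full tip set.
#' @export
rpd <- function(tree, tips) {
  comparison <- tree
  comparison$edge.length <- rep(1, nrow(tree$edge))
  num <- faith_pd(tree, tips) / total_length(tree)
  den <- faith_pd(comparison, tips) / total_length(comparison)
  if (den == 0) stop("comparison-tree PD is zero", call. = FALSE)
  num / den
}

#' Null-model specification for standardized effect sizes
#'
#' The null draws tip sets of the observed size uniformly without replacement
#' from the pool of all tree tips.
#'
#' @param n_randomizations Number of Monte Carlo draws (default 999).
#' @param seed Integer seed; required for `monte_carlo` mode.
#' @param mode `"monte_carlo"` or `"exhaustive"` (full enumeration of all
#'   `choose(pool, k)` subsets, allowed only up to `exhaustive_cap`).
#' @param exhaustive_cap Maximum number of subsets enumerated exhaustively.
#' @return A `null_spec` list.
#' @export
null_spec <- function(n_randomizations = 999, seed = NULL,
                      mode = c("monte_carlo", "exhaustive"),
                      exhaustive_cap = 200000) {
  mode <- match.arg(mode)
  if (n_randomizations < 1) stop("n_randomizations must be >= 1", call. = FALSE)
  if (mode == "monte_carlo" && is.null(seed)) {
    stop("monte_carlo null requires a seed", call. = FALSE)
  }
  structure(list(n_randomizations = as.integer(n_randomizations),
                 seed = seed, mode = mode,
                 exhaustive_cap = exhaustive_cap),
            class = "null_spec")
}

# Null PD values for draws encoded as an indicator matrix Z (draws x tips).
.null_pd_values <- function(Z, etm) {
  counts <- Z %*% t(etm$M)
  (counts > 0) %*% etm$edge_length
}

# Null MPD values for indicator matrix Z and patristic matrix D; k tips/draw.
.null_mpd_values <- function(Z, D, k) {
  rowSums((Z %*% D) * Z) / (k * (k - 1))
}

.draw_indicator <- function(n_draws, pool_size, k) {
  Z <- matrix(0, nrow = n_draws, ncol = pool_size)
  for (j in seq_len(n_draws)) {
    Z[j, sample.int(pool_size, k)] <- 1
  }
  Z
}

.enumerate_indicator <- function(pool_size, k) {
  sets <- utils::combn(pool_size, k)
  Z <- matrix(0, nrow = ncol(sets), ncol = pool_size)
  for (j in seq_len(ncol(sets))) Z[j, sets[, j]] <- 1
  Z
}

#' Standardized effect size of PD or MPD
#'
#' Standardizes the observed metric against random tip sets of the same size
#' drawn uniformly without replacement from the pool of all tree tips.
#' Positive values indicate phylogenetic overdispersion, negative values
#' phylogenetic clustering. When the null has zero spread (e.g. the tip set
#' is the whole pool) the SES is reported as `NA` with a reason, not an error.
#'
#' @param tree A `phylo` object.
#' @param tips Character vector of at least two tip labels.
#' @param metric `"PD"` or `"MPD"`.
#' @param null A [null_spec()].
#' @return A list with `observed`, `null_mean`, `null_sd`, `ses`, and
#'   `reason` (`NA` unless the SES is undefined).
#' @export
ses_metric <- function(tree, tips, metric = c("PD", "MPD"), null) {
  metric <- match.arg(metric)
  stopifnot(inherits(null, "null_spec"))
  idx <- .tip_indices(tree, tips)
  k <- length(idx)
  if (k < 2L) stop("SES requires at least 2 tips", call. = FALSE)
  pool_size <- ape::Ntip(tree)

  if (null$mode == "exhaustive") {
    n_sets <- choose(pool_size, k)
    if (n_sets > null$exhaustive_cap) {
      stop("exhaustive enumeration of ", n_sets,
           " subsets exceeds cap ", null$exhaustive_cap, call. = FALSE)
    }
    Z <- .enumerate_indicator(pool_size, k)
  } else {
    set.seed(null$seed)
    Z <- .draw_indicator(null$n_randomizations, pool_size, k)
  }

  if (metric == "PD") {
    etm <- edge_tip_matrix(tree)
    observed <- faith_pd(tree, tree$tip.label[idx])
    null_vals <- as.numeric(.null_pd_values(Z, etm))
  } else {
    D <- patristic_matrix(tree)[tree$tip.label, tree$tip.label]
    observed <- mpd(tree, tree$tip.label[idx], dist = D)
    null_vals <- as.numeric(.null_mpd_values(Z, D, k))
  }

  null_mean <- mean(null_vals)
  # exhaustive enumeration IS the full null distribution, so its spread is
  # the population sd; Monte Carlo estimates it with the sample sd
  null_sd <- if (null$mode == "exhaustive") {
    sqrt(mean((null_vals - null_mean)^2))
  } else {
    stats::sd(null_vals)
  }
  scale_ref <- max(abs(null_vals), 1)
  if (!is.finite(null_sd) || null_sd <= 1e-12 * scale_ref) {
    return(list(observed = observed, null_mean = null_mean, null_sd = null_sd,
                ses = NA_real_, reason = "null distribution has zero spread"))
  }
  list(observed = observed, null_mean = null_mean, null_sd = null_sd,
       ses = (observed - null_mean) / null_sd, reason = NA_character_)
}

.as_assemblage_list <- function(assemblages) {
  if (is.matrix(assemblages) || is.data.frame(assemblages) &&
      !all(c("region_id", "species") %in% names(assemblages))) {
    m <- as.matrix(assemblages)
    if (is.null(rownames(m)) || is.null(colnames(m))) {
      stop("wide assemblage matrix needs region row names and species column names",
           call. = FALSE)
    }
    return(lapply(stats::setNames(seq_len(nrow(m)), rownames(m)),
                  function(i) colnames(m)[m[i, ] > 0]))
  }
  df <- as.data.frame(assemblages)
  split(as.character(df$species), as.character(df$region_id))
}

#' Compute the five phylogenetic-structure metrics for every region
#'
#' For each region, computes raw Faith PD, area-corrected PD, MPD, RPD, and
#' the standardized effect sizes of PD and MPD under the uniform tip-sampling
#' null. Species absent from the tree are dropped (count messaged); regions
#' with no matched species are excluded with a warning. Deterministic given
#' the null seed: regions are processed in sorted region-id order.
#'
#' @param tree A `phylo` object whose tips are the species pool.
#' @param assemblages Long data frame (`region_id`, `species`) or a wide
#'   region-by-species incidence matrix.
#' @param regions Data frame with `region_id` and `area_km2`.
#' @param null A [null_spec()] for the SES metrics.
#' @return A tibble with columns `region_id`, `richness`, `PD_raw`, `PD`,
#'   `MPD`, `RPD`, `PD_ses`, `MPD_ses` (fixed order). SES columns are `NA`
#'   where richness < 2 or the null has zero spread; MPD is `NA` where
#'   richness < 2.
#' @export
compute_metric_table <- function(tree, assemblages, regions, null) {
  stopifnot(inherits(null, "null_spec"))
  asm <- .as_assemblage_list(assemblages)
  all_sp <- unique(unlist(asm, use.names = FALSE))
  unmatched <- setdiff(all_sp, tree$tip.label)
  if (length(unmatched) > 0) {
    message(length(unmatched), " assemblage species not in tree; dropped")
    asm <- lapply(asm, function(x) setdiff(x, unmatched))
  }
  empty <- names(asm)[lengths(asm) == 0L]
  if (length(empty) > 0) {
    warning(length(empty), " region(s) with no matched species excluded: ",
            paste(utils::head(empty, 5), collapse = ", "), call. = FALSE)
    asm <- asm[lengths(asm) > 0L]
  }
  if (length(asm) == 0L) stop("no regions with matched species", call. = FALSE)
  asm <- asm[order(names(asm))]

  regions <- as.data.frame(regions)
  area <- stats::setNames(regions$area_km2, as.character(regions$region_id))

  D <- patristic_matrix(tree)[tree$tip.label, tree$tip.label]
  etm <- edge_tip_matrix(tree)
  comparison <- tree
  comparison$edge.length <- rep(1, nrow(tree$edge))
  etm_unit <- edge_tip_matrix(comparison)
  tot <- total_length(tree)
  tot_unit <- nrow(tree$edge)
  pool_size <- ape::Ntip(tree)

  if (null$mode == "monte_carlo") set.seed(null$seed)

  rows <- lapply(names(asm), function(rid) {
    tips <- asm[[rid]]
    idx <- match(tips, tree$tip.label)
    k <- length(idx)
    zrow <- numeric(pool_size); zrow[idx] <- 1
    pd_raw <- as.numeric(.null_pd_values(matrix(zrow, 1), etm))
    pd_unit <- as.numeric(.null_pd_values(matrix(zrow, 1), etm_unit))
    rpd_val <- (pd_raw / tot) / (pd_unit / tot_unit)
    mpd_val <- if (k >= 2) mean(D[idx, idx][upper.tri(matrix(0, k, k))]) else NA_real_

    pd_ses <- mpd_ses <- NA_real_
    if (k >= 2) {
      Z <- if (null$mode == "exhaustive") {
        if (choose(pool_size, k) > null$exhaustive_cap) {
          stop("exhaustive enumeration exceeds cap for region ", rid, call. = FALSE)
        }
        .enumerate_indicator(pool_size, k)
      } else {
        .draw_indicator(null$n_randomizations, pool_size, k)
      }
      pd_null <- as.numeric(.null_pd_values(Z, etm))
      mpd_null <- as.numeric(.null_mpd_values(Z, D, k))
      # population sd under full enumeration, sample sd under Monte Carlo
      pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
      sd_pd <- if (null$mode == "exhaustive") pop_sd(pd_null) else stats::sd(pd_null)
      sd_mpd <- if (null$mode == "exhaustive") pop_sd(mpd_null) else stats::sd(mpd_null)
      if (is.finite(sd_pd) && sd_pd > 1e-12 * max(abs(pd_null), 1)) {
        pd_ses <- (pd_raw - mean(pd_null)) / sd_pd
      }
      if (is.finite(sd_mpd) && sd_mpd > 1e-12 * max(abs(mpd_null), 1)) {
        mpd_ses <- (mpd_val - mean(mpd_null)) / sd_mpd
      }
    }
    a <- area[[rid]]
    tibble::tibble(region_id = rid, richness = k, PD_raw = pd_raw,
                   PD = if (is.null(a) || is.na(a)) NA_real_ else area_corrected_pd(pd_raw, a),
                   MPD = mpd_val, RPD = rpd_val,
                   PD_ses = pd_ses, MPD_ses = mpd_ses)
  })
  dplyr::bind_rows(rows)
}

#' Write a metric table as tab-delimited text with fixed column order
#' @param metric_table Output of [compute_metric_table()].
#' @param path File path.
#' @export
write_metric_table <- function(metric_table, path) {
  cols <- c("region_id", "richness", "PD_raw", "PD", "MPD", "RPD",
            "PD_ses", "MPD_ses")
  readr::write_tsv(metric_table[, cols], path)
}
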