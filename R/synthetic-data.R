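#' Configuration of a synthetic world
#'
#' Bundles every parameter of the generator. Defaults describe the standard
#' study conditions: a 300-species flora on a dated, high-turnover
#' birth-death tree rescaled to a fixed crown age, two Brownian niche axes
#' rooted in a warm, moist climate, a 12 x 12 grid of regions spanning a
#' strong latitudinal temperature gradient with spatially autocorrelated
#' surfaces, and niche-filtered assemblages. The default regime makes the
#' temperature axis the binding assembly filter (tip-level spread of the
#' temperature optima is comparable to the thermal tolerance) while the
#' precipitation filter is deliberately weak (tolerance of several standard
#' deviations), reflecting a clade in which cold tolerance is the rare,
#' phylogenetically clustered trait and drought strategies are widespread.
#'
#' @param n_tips Number of extant species (>= 2).
#' @param birth,death Birth and death rates (events/lineage/Myr); `death`
#'   must be strictly below `birth`. The default high-turnover pair gives
#'   many recent radiations nested in few old lineages.
#' @param crown_age Crown age of the phylogeny (Myr); the simulated tree is
#'   rescaled to exactly this depth so that niche divergence accumulated to
#'   the tips is comparable across worlds.
#' @param n_cold_clades,cold_shift Number of shallowly nested clades that
#'   receive a discrete cold displacement of their temperature optima, and
#'   the displacement magnitude range (degC); see [assign_cold_clades()].
#'   Cold tolerance is thereby a derived trait of a few young radiations
#'   rather than a chance product of the Brownian background.
#' @param bm_sigma2 Named Brownian rates per niche axis
#'   (`temperature` in degC^2/Myr, `precipitation` in mm^2/Myr).
#' @param root_state Named ancestral niche optima (degC, mm).
#' @param grid_nx,grid_ny Grid dimensions (regions = nx * ny).
#' @param n_subcells Sub-cell samples per region for heterogeneity columns.
#' @param rho Spatial autocorrelation of environmental surfaces, |rho| < 1.
#' @param epoch_shift Named magnitudes of the glacial-to-present climate
#'   shift (degC, mm).
#' @param tolerance Named niche breadths for the occurrence filter (degC, mm).
#' @param relief_scale Multiplier on within-region topographic relief; 0
#'   gives perfectly homogeneous regions (all `*_sd` columns zero).
#' @param seed Master seed; every random draw derives from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_tips = 300, birth = 0.4, death = 0.3,
                             crown_age = 100, n_cold_clades = 3,
                             cold_shift = c(12, 22),
                             bm_sigma2 = c(temperature = 0.15, precipitation = 4000),
                             root_state = c(temperature = 25, precipitation = 1800),
                             grid_nx = 12, grid_ny = 12,
                             n_subcells = 25, rho = 0.8,
                             epoch_shift = c(temperature = 5, precipitation = 300),
                             tolerance = c(temperature = 10, precipitation = 2500),
                             relief_scale = 1, seed = 1) {
  stopifnot(n_tips >= 2, birth >= 0, death >= 0, abs(rho) < 1, crown_age > 0,
            n_cold_clades >= 0, length(cold_shift) == 2,
            all(tolerance > 0), all(bm_sigma2 >= 0), relief_scale >= 0)
  if (death >= birth) stop("death rate must be below birth rate", call. = FALSE)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate a dated birth-death phylogeny with a fixed number of extant tips
#'
#' The realized depth of a birth-death simulation varies widely between
#' replicates; when `crown_age` is given the tree is rescaled to exactly
#' that depth, so Brownian niche divergence accumulated to the tips is
#' comparable across simulated worlds.
#'
#' @param n_tips Number of extant tips (>= 2).
#' @param birth,death Rates per lineage per Myr; `death < birth`.
#' @param seed Integer seed.
#' @param crown_age Optional fixed crown age (Myr) to rescale the tree to.
#' @return An ultrametric `phylo` with exactly `n_tips` tips, labels
#'   `s1..sn`.
#' @export
simulate_tree <- function(n_tips, birth, death, seed, crown_age = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (death >= birth) stop("death rate must be below birth rate", call. = FALSE)
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = birth, death = death)
  tree$tip.label <- paste0("s", seq_len(n_tips))
  if (!is.null(crown_age)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * (crown_age / depth)
  }
  tree
}

#' Evolve a continuous niche trait by Brownian motion along a tree
#'
#' @param tree A `phylo` object.
#' @param sigma2 Brownian rate (variance per unit branch length), >= 0.
#' @param root_state Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip states.
#' @export
evolve_bm <- function(tree, sigma2, root_state, seed) {
  stopifnot(sigma2 >= 0)
  set.seed(seed)
  if (sigma2 == 0) {
    return(stats::setNames(rep(root_state, ape::Ntip(tree)), tree$tip.label))
  }
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2),
                  root.value = root_state)
}

#' Shift the niche optima of a few shallowly nested clades toward cold
#'
#' Models cold tolerance as a derived trait: a small number of mid-sized,
#' shallowly nested clades receive a discrete cold displacement of their
#' temperature optima on top of the Brownian background. Under plain
#' Brownian motion, whether the cold tail of the niche cloud is a coherent
#' recent radiation or an isolated deep lineage is left to chance; this
#' step fixes the documented structure (cold floras assembled from few
#' young radiations) explicitly.
#'
#' Candidate clades hold between `size_range[1]` and `size_range[2]` of all
#' tips and have a crown age of at most `max_age_frac` of the tree depth;
#' `n_clades` non-overlapping candidates are drawn at random and each has
#' its tips shifted by minus `runif(1, shift_range[1], shift_range[2])`.
#'
#' @param tree A `phylo` object.
#' @param optima Named tip vector of temperature optima.
#' @param seed Integer seed.
#' @param n_clades Number of cold clades to draw (fewer if the tree offers
#'   fewer disjoint candidates).
#' @param shift_range Range of the cold displacement magnitude (degC).
#' @param size_range Clade size bounds as fractions of the number of tips.
#' @param max_age_frac Maximum crown age of a candidate clade, as a
#'   fraction of total tree depth.
#' @return List: `optima` (shifted vector) and `clades` (tibble with
#'   `node`, `n_tips`, `shift`).
#' @export
assign_cold_clades <- function(tree, optima, seed, n_clades = 3,
                               shift_range = c(12, 22),
                               size_range = c(0.04, 0.12),
                               max_age_frac = 0.4) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  depth <- max(ape::node.depth.edgelength(tree))
  ages <- node_ages(tree)
  internal <- (n + 1):(n + tree$Nnode)
  tips_of <- lapply(internal, function(nd)
    ape::extract.clade(tree, nd)$tip.label)
  sizes <- lengths(tips_of)
  ok <- sizes >= size_range[1] * n & sizes <= size_range[2] * n &
    ages[internal] <= max_age_frac * depth
  cand <- internal[ok]
  chosen <- integer(0)
  chosen_tips <- character(0)
  if (n_clades == 0 || length(cand) == 0) {
    return(list(optima = optima,
                clades = tibble::tibble(node = integer(),
                                        n_tips = integer(),
                                        shift = numeric())))
  }
  for (nd in cand[sample.int(length(cand))]) {
    tl <- tips_of[[match(nd, internal)]]
    if (!any(tl %in% chosen_tips)) {
      chosen <- c(chosen, nd)
      chosen_tips <- c(chosen_tips, tl)
      if (length(chosen) >= n_clades) break
    }
  }
  shifts <- stats::runif(length(chosen), shift_range[1], shift_range[2])
  for (i in seq_along(chosen)) {
    tl <- tips_of[[match(chosen[i], internal)]]
    optima[tl] <- optima[tl] - shifts[i]
  }
  list(optima = optima,
       clades = tibble::tibble(
         node = chosen,
         n_tips = vapply(chosen, function(nd)
           length(tips_of[[match(nd, internal)]]), integer(1)),
         shift = shifts))
}

#' Lay out gridded regions with continents, centroids and areas
#'
#' Regions sit on a lon/lat grid spanning a wide latitudinal range; six
#' contiguous blocks (3 longitude bands x 2 latitude bands) serve as
#' biogeographic continents; areas are drawn log-uniformly in
#' `[10^3, 10^6]` km^2 so the area correction of PD is exercised.
#'
#' @param nx,ny Grid dimensions.
#' @param seed Integer seed (areas are random).
#' @return Tibble: `region_id`, `lon`, `lat`, `continent`, `area_km2`.
#' @export
make_grid_regions <- function(nx, ny, seed) {
  set.seed(seed)
  lon <- seq(-150, 150, length.out = nx)
  lat <- seq(-60, 60, length.out = ny)
  g <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  lon_band <- pmin(3L, 1L + (g$ix - 1L) %/% ceiling(nx / 3))
  lat_band <- pmin(2L, 1L + (g$iy - 1L) %/% ceiling(ny / 2))
  continents <- c("Africa", "Asia", "Australasia",
                  "Europe", "NorthernAmerica", "SouthernAmerica")
  tibble::tibble(
    region_id = sprintf("r%03d", seq_len(nrow(g))),
    lon = lon[g$ix], lat = lat[g$iy],
    continent = continents[(lat_band - 1L) * 3L + lon_band],
    area_km2 = 10^stats::runif(nrow(g), 3, 6)
  )
}

# One spatially autocorrelated unit-variance surface: x = (I - rho W)^{-1} e.
.sar_surface <- function(Wm, rho) {
  n <- nrow(Wm)
  A <- diag(n) - rho * Wm
  x <- tryCatch(solve(A, stats::rnorm(n)),
                error = function(e) stop("singular (I - rho W)", call. = FALSE))
  as.numeric(x / stats::sd(x))
}

#' Generate the 13-variable environment table over gridded regions
#'
#' Current-climate surfaces combine a latitudinal gradient with spatially
#' autocorrelated noise drawn from a simultaneous autoregressive process.
#' Historical-change columns come from a simulated glacial epoch: the past
#' surface is the present minus a shift surface, the anomaly is the absolute
#' present-past difference, and the velocity divides the temporal rate
#' (anomaly per year over 21,000 yr) by the local spatial gradient
#' (mean neighbour difference per km, floored at `1e-6` units/km to avoid
#' infinite velocities on flat surfaces). Heterogeneity columns are standard
#' deviations over sub-cell values whose spread scales with a per-region
#' topographic relief.
#'
#' @param regions Output of [make_grid_regions()].
#' @param W Optional `spatial_weights` for the surfaces (default: 4-nearest
#'   neighbours on the centroids).
#' @param rho Surface autocorrelation, |rho| < 1.
#' @param epoch_shift Named shift magnitudes (`temperature`, `precipitation`).
#' @param n_subcells Sub-cell samples per region.
#' @param relief_scale Multiplier on within-region relief (0 = homogeneous).
#' @param seed Integer seed.
#' @return List with `env` (tibble: `region_id` + the 13 variables) and
#'   `subcells` (long tibble of sub-cell elevation/temperature/precipitation).
#' @export
generate_environment <- function(regions, W = NULL, rho = 0.8,
                                 epoch_shift = c(temperature = 5, precipitation = 300),
                                 n_subcells = 25, relief_scale = 1, seed = 1) {
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (is.null(W)) W <- build_weights(regions, k = 4)
  Wm <- .weights_matrix(W)
  n <- nrow(regions)
  set.seed(seed)
  s <- replicate(10, .sar_surface(Wm, rho))
  latw <- abs(regions$lat) / max(abs(regions$lat), 1)

  T_mean <- 28 - 33 * latw + 3 * s[, 1]
  T_min <- T_mean - (4 + 10 * latw + 2 * abs(s[, 2]))
  T_seas <- pmax(0, 2 + 10 * latw + 1.5 * s[, 3])
  P_mean <- pmax(50, 2600 - 2000 * latw + 400 * s[, 4])
  P_min <- P_mean / 12 * stats::plogis(0.5 - 2 * latw + 0.8 * s[, 5])
  P_seas <- pmax(0, 40 + 30 * latw + 10 * s[, 6])

  # Glacial epoch: the shift pattern is dominated by regional structure
  # (ice-sheet geometry, circulation), with only a mild latitudinal loading,
  # so historical change is not simply a rescaled copy of current climate.
  # Anomaly = magnitude of the present-past difference; velocity = temporal
  # rate / spatial rate.
  t_shift <- epoch_shift[["temperature"]] * (0.6 + 0.25 * latw + 0.8 * s[, 7])
  p_shift <- epoch_shift[["precipitation"]] * (0.6 + 0.25 * latw + 0.8 * s[, 8])
  T_anom <- abs(t_shift)
  P_anom <- abs(p_shift)
  T_vel <- .climate_velocity(T_mean, T_anom, Wm, W$dist_km)
  P_vel <- .climate_velocity(P_mean, P_anom, Wm, W$dist_km)

  elev <- pmax(0, 600 + 700 * s[, 9])
  relief <- relief_scale * exp(stats::rnorm(n, log(150), 0.6))
  sub <- lapply(seq_len(n), function(i) {
    e <- elev[i] + stats::rnorm(n_subcells, 0, relief[i])
    tibble::tibble(
      region_id = regions$region_id[i],
      elev = e,
      temp = T_mean[i] - 0.0065 * (e - mean(e)) +
        stats::rnorm(n_subcells, 0, 0.05 * relief_scale),
      precip = pmax(0, P_mean[i] + 0.5 * (e - mean(e)) +
                      stats::rnorm(n_subcells, 0, 10 * relief_scale))
    )
  })
  subcells <- dplyr::bind_rows(sub)
  sds <- vapply(sub, function(d) c(stats::sd(d$elev), stats::sd(d$temp),
                                   stats::sd(d$precip)), numeric(3))

  env <- tibble::tibble(
    region_id = regions$region_id,
    T_mean = T_mean, T_min = T_min, T_seas = T_seas,
    P_mean = P_mean, P_min = P_min, P_seas = P_seas,
    T_anom = T_anom, T_vel = T_vel, P_anom = P_anom, P_vel = P_vel,
    E_sd = sds[1, ], T_sd = sds[2, ], P_sd = sds[3, ]
  )
  list(env = env, subcells = subcells)
}

# Velocity of climate change: |temporal change per yr| / spatial gradient
# (units/km), with the gradient taken as the neighbour-weighted mean absolute
# difference per km and floored at 1e-6 units/km.
.climate_velocity <- function(present, anomaly, Wm, dist_km) {
  n <- length(present)
  grad <- vapply(seq_len(n), function(i) {
    nb <- which(Wm[i, ] > 0)
    if (length(nb) == 0) return(0)
    sum(Wm[i, nb] * abs(present[i] - present[nb]) / pmax(dist_km[i, nb], 1e-9))
  }, numeric(1))
  (anomaly / 21000) / pmax(grad, 1e-6)
}

#' Assemble regional floras by environmental niche filtering
#'
#' A species occurs in a region exactly when its niche optimum lies within
#' the axis tolerance of the region's mean climate on every axis
#' (temperature vs `T_mean`, precipitation vs `P_mean`). Deterministic.
#'
#' @param niches Data frame or matrix: rows = species (rownames or `species`
#'   column), columns `temperature` and `precipitation`.
#' @param env Environment table with `region_id`, `T_mean`, `P_mean`.
#' @param tolerance Named niche breadths.
#' @return Long tibble (`region_id`, `species`); regions with no species
#'   simply have no rows.
#' @export
assemble <- function(niches, env, tolerance) {
  niches <- as.data.frame(niches)
  if ("species" %in% names(niches)) {
    rownames(niches) <- niches$species
  }
  sp <- rownames(niches)
  okT <- abs(outer(env$T_mean, niches$temperature, "-")) <= tolerance[["temperature"]]
  okP <- abs(outer(env$P_mean, niches$precipitation, "-")) <= tolerance[["precipitation"]]
  occ <- okT & okP
  idx <- which(occ, arr.ind = TRUE)
  tibble::tibble(region_id = env$region_id[idx[, 1]],
                 species = sp[idx[, 2]]) |>
    dplyr::arrange(.data$region_id, .data$species)
}

#' Simulate a complete synthetic world
#'
#' Derives independent sub-seeds from the master seed, then simulates the
#' phylogeny, the Brownian niche optima, the gridded regions, the
#' environment, and the niche-filtered assemblages.
#'
#' @param config A [synthetic_config()].
#' @return List: `tree`, `niches` (tibble), `regions`, `env`, `subcells`,
#'   `assemblages`, `cold_clades`, `config`.
#' @export
simulate_world <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 6)
  tree <- simulate_tree(config$n_tips, config$birth, config$death, seeds[1],
                        crown_age = config$crown_age)
  opt_T <- evolve_bm(tree, config$bm_sigma2[["temperature"]],
                     config$root_state[["temperature"]], seeds[2])
  cold <- assign_cold_clades(tree, opt_T, seeds[6],
                             n_clades = config$n_cold_clades,
                             shift_range = config$cold_shift)
  opt_T <- cold$optima
  opt_P <- evolve_bm(tree, config$bm_sigma2[["precipitation"]],
                     config$root_state[["precipitation"]], seeds[3])
  niches <- tibble::tibble(species = tree$tip.label,
                           temperature = unname(opt_T[tree$tip.label]),
                           precipitation = unname(opt_P[tree$tip.label]))
  regions <- make_grid_regions(config$grid_nx, config$grid_ny, seeds[4])
  envres <- generate_environment(regions, rho = config$rho,
                                 epoch_shift = config$epoch_shift,
                                 n_subcells = config$n_subcells,
                                 relief_scale = config$relief_scale,
                                 seed = seeds[5])
  assemblages <- assemble(niches, envres$env, config$tolerance)
  list(tree = tree, niches = niches, regions = regions,
       env = envres$env, subcells = envres$subcells,
       assemblages = assemblages, cold_clades = cold$clades,
       config = config)
}

#' Write a synthetic world to disk in the formats the pipeline reads
#'
#' Writes the Newick tree, the long assemblage table, the region table, the
#' environment table, and a JSON manifest recording the configuration.
#'
#' @param world Output of [simulate_world()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(world$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(world$assemblages, file.path(dir, "assemblages.tsv"))
  readr::write_tsv(world$regions, file.path(dir, "regions.tsv"))
  readr::write_tsv(world$env, file.path(dir, "environment.tsv"))
  cfg <- world$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
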