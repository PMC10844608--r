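test_that("birth-death trees are ultrametric, sized and seed-deterministic", {
  tree <- simulate_tree(64, 0.2, 0, seed = 1)
  expect_equal(ape::Ntip(tree), 64)
  expect_true(is_ultrametric_tol(tree, 1e-9))

  t2 <- simulate_tree(64, 0.2, 0, seed = 1)
  expect_identical(write_newick(tree), write_newick(t2))

  cherry <- simulate_tree(2, 0.3, 0.1, seed = 2)
  depths <- ape::node.depth.edgelength(cherry)[1:2]
  expect_equal(depths[1], depths[2])

  expect_error(simulate_tree(10, 0.1, 0.2, seed = 1), "death rate")
})

test_that("Brownian evolution has the right degenerate case and covariance", {
  tree <- random_coal_tree(8, 3)
  flat <- evolve_bm(tree, 0, root_state = 12, seed = 4)
  expect_true(all(flat == 12))

  # empirical tip covariance ~ sigma2 x shared root-path length
  sigma2 <- 2.5
  reps <- vapply(1:400, function(r) evolve_bm(tree, sigma2, 0, seed = r),
                 numeric(8))
  emp <- cov(t(reps))
  shared <- ape::vcv(tree)
  expect_equal(mean(diag(emp) / diag(sigma2 * shared)), 1, tolerance = 0.15)
  off <- upper.tri(shared) & sigma2 * shared > 0.05 * max(shared)
  expect_equal(mean(emp[off] / (sigma2 * shared)[off]), 1, tolerance = 0.2)

  # closer relatives have more similar states
  D <- patristic_matrix(tree)
  pair_min <- which(D == min(D[D > 0]), arr.ind = TRUE)[1, ]
  pair_max <- which(D == max(D), arr.ind = TRUE)[1, ]
  d_close <- mean(abs(reps[pair_min[1], ] - reps[pair_min[2], ]))
  d_far <- mean(abs(reps[pair_max[1], ] - reps[pair_max[2], ]))
  expect_lt(d_close, d_far)
})

test_that("cold-clade displacement shifts whole shallow clades and only them", {
  tree <- simulate_tree(120, 0.4, 0.3, seed = 20, crown_age = 100)
  base <- evolve_bm(tree, 0.15, root_state = 25, seed = 21)
  res <- assign_cold_clades(tree, base, seed = 22, n_clades = 3,
                            shift_range = c(12, 22))
  expect_lte(nrow(res$clades), 3)
  expect_gte(nrow(res$clades), 1)
  moved <- names(base)[res$optima != base]
  expect_equal(sort(unique(res$optima[moved] - base[moved])),
               sort(-res$clades$shift))
  ages <- node_ages(tree)
  for (i in seq_len(nrow(res$clades))) {
    cl <- ape::extract.clade(tree, res$clades$node[i])$tip.label
    # every clade member moved by the clade's shift, no one else did
    expect_true(all(res$optima[cl] - base[cl] == -res$clades$shift[i]))
    expect_true(all(res$clades$shift >= 12 & res$clades$shift <= 22))
    # candidates are mid-sized and shallowly nested
    expect_lte(length(cl), 0.12 * 120)
    expect_gte(length(cl), 0.04 * 120)
    expect_lte(ages[res$clades$node[i]], 0.4 * 100)
  }
  expect_equal(length(moved), sum(res$clades$n_tips))

  # determinism and the empty case
  res2 <- assign_cold_clades(tree, base, seed = 22, n_clades = 3,
                             shift_range = c(12, 22))
  expect_identical(res$optima, res2$optima)
  res0 <- assign_cold_clades(tree, base, seed = 22, n_clades = 0)
  expect_identical(res0$optima, base)
  expect_equal(nrow(res0$clades), 0)
})

test_that("a fixed crown age rescales depth without touching topology", {
  t1 <- simulate_tree(50, 0.4, 0.3, seed = 30)
  t2 <- simulate_tree(50, 0.4, 0.3, seed = 30, crown_age = 100)
  expect_equal(max(ape::node.depth.edgelength(t2)), 100, tolerance = 1e-12)
  expect_identical(t1$edge, t2$edge)
  expect_equal(t2$edge.length / t1$edge.length,
               rep(100 / max(ape::node.depth.edgelength(t1)),
                   length(t1$edge.length)))
})

test_that("the environment table has exactly the 13 variables with valid ranges", {
  regions <- make_grid_regions(6, 6, seed = 5)
  out <- generate_environment(regions, rho = 0.6, n_subcells = 9, seed = 6)
  expect_identical(colnames(out$env),
                   c("region_id", "T_mean", "T_min", "T_seas", "P_mean",
                     "P_min", "P_seas", "T_anom", "T_vel", "P_anom", "P_vel",
                     "E_sd", "T_sd", "P_sd"))
  env <- out$env
  expect_true(all(is.finite(as.matrix(env[, -1]))))
  expect_true(all(env$P_mean >= env$P_min))
  expect_true(all(env$P_min >= 0))
  expect_true(all(env$T_min <= env$T_mean))
  expect_true(all(env[, c("T_seas", "P_seas", "T_anom", "P_anom",
                          "T_vel", "P_vel", "E_sd", "T_sd", "P_sd")] >= 0))
})

test_that("homogeneous regions give zero heterogeneity columns", {
  regions <- make_grid_regions(4, 4, seed = 7)
  out <- generate_environment(regions, rho = 0.5, n_subcells = 6,
                              relief_scale = 0, seed = 8)
  expect_true(all(out$env$E_sd == 0))
  expect_true(all(out$env$T_sd == 0))
  expect_true(all(out$env$P_sd == 0))
})

test_that("surface autocorrelation responds to rho as Moran's I predicts", {
  regions <- make_grid_regions(7, 7, seed = 9)
  W <- build_weights(regions, k = 4)
  n <- nrow(regions)
  i0 <- i8 <- numeric(60)
  for (r in 1:60) {
    e0 <- generate_environment(regions, W = W, rho = 0, n_subcells = 2,
                               seed = 100 + r)$env
    e8 <- generate_environment(regions, W = W, rho = 0.8, n_subcells = 2,
                               seed = 100 + r)$env
    # strip the deterministic latitudinal part before testing the noise
    i0[r] <- morans_i(resid(lm(e0$T_mean ~ abs(regions$lat))), W)
    i8[r] <- morans_i(resid(lm(e8$T_mean ~ abs(regions$lat))), W)
  }
  se0 <- sd(i0) / sqrt(length(i0))
  expect_lt(abs(mean(i0) - (-1 / (n - 1))), 4 * se0)
  expect_gt(mean(i8), mean(i0))
})

test_that("assembly matches the brute-force niche filter", {
  cfg <- small_world_config(seed = 10)
  w <- simulate_world(cfg)
  tol <- cfg$tolerance
  # brute-force double loop
  expected <- 0L
  for (i in seq_len(nrow(w$env))) {
    for (j in seq_len(nrow(w$niches))) {
      if (abs(w$niches$temperature[j] - w$env$T_mean[i]) <= tol[["temperature"]] &&
          abs(w$niches$precipitation[j] - w$env$P_mean[i]) <= tol[["precipitation"]]) {
        expected <- expected + 1L
      }
    }
  }
  expect_equal(nrow(w$assemblages), expected)

  # vacuous and total filters
  every <- assemble(w$niches, w$env, c(temperature = Inf, precipitation = Inf))
  expect_equal(nrow(every), nrow(w$env) * nrow(w$niches))
  none <- assemble(w$niches, w$env, c(temperature = 1e-9, precipitation = 1e-9))
  expect_equal(nrow(none), 0L)
})

test_that("worlds are bit-reproducible from the master seed", {
  w1 <- simulate_world(small_world_config(seed = 13))
  w2 <- simulate_world(small_world_config(seed = 13))
  expect_identical(write_newick(w1$tree), write_newick(w2$tree))
  expect_identical(w1$env, w2$env)
  expect_identical(w1$assemblages, w2$assemblages)
  expect_identical(w1$regions, w2$regions)
})

test_that("richness increases with temperature under warm conserved niches", {
  ok <- 0L
  for (s in 1:10) {
    w <- simulate_world(small_world_config(seed = 300 + s))
    rich <- table(w$assemblages$region_id)
    d <- merge(data.frame(region_id = names(rich), rich = as.numeric(rich)),
               w$env, by = "region_id")
    if (cor(d$rich, d$T_mean, method = "spearman") > 0) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})
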