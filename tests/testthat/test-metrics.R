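test_that("faith_pd matches the stated small-tree values", {
  tree <- toy_tree()
  expect_equal(faith_pd(tree, c("A", "B", "C")), 5)
  expect_equal(faith_pd(tree, c("A", "B")), 3)
  expect_equal(faith_pd(tree, "C"), 2)
  expect_error(faith_pd(tree, "Z"), "unknown tip")
  expect_error(faith_pd(tree, character(0)), "non-empty")
})

test_that("faith_pd, mpd and rpd match brute-force oracles on all subsets", {
  for (seed in 1:3) {
    tree <- random_coal_tree(7, seed)
    for (tips in all_tip_subsets(tree)) {
      expect_equal(faith_pd(tree, tips), bf_pd(tree, tips), tolerance = 1e-12)
      expect_equal(rpd(tree, tips), bf_rpd(tree, tips), tolerance = 1e-12)
      if (length(tips) >= 2) {
        expect_equal(mpd(tree, tips), bf_mpd(tree, tips), tolerance = 1e-12)
      }
    }
  }
})

test_that("faith_pd agrees with picante's rooted PD and is monotone", {
  skip_if_not_installed("picante")
  tree <- random_coal_tree(10, 4)
  sets <- list(c("t1", "t2"), c("t1", "t2", "t5"), tree$tip.label[1:7])
  comm <- t(vapply(sets, function(s) tree$tip.label %in% s, logical(10))) * 1
  colnames(comm) <- tree$tip.label
  pic <- picante::pd(comm, tree, include.root = TRUE)$PD
  ours <- vapply(sets, function(s) faith_pd(tree, s), numeric(1))
  expect_equal(ours, pic, tolerance = 1e-10)
  # superset monotonicity, bounded by total length
  expect_true(ours[1] <= ours[2])
  expect_true(all(ours <= total_length(tree)))
})

test_that("area correction divides by log10(area) with guards", {
  expect_equal(area_corrected_pd(100, 1e4), 25)
  expect_warning(v <- area_corrected_pd(7, 10), "area")
  expect_equal(v, 7)
  expect_error(area_corrected_pd(5, 1), "area")
})

test_that("mpd requires pairs and matches the all-pairs mean", {
  tree <- toy_tree()
  expect_equal(mpd(tree, c("A", "B")), 2)
  expect_equal(mpd(tree, c("A", "B", "C")), 10 / 3)
  expect_error(mpd(tree, "A"), "at least 2")
})

test_that("rpd equals 1 in degenerate cases and is scale invariant", {
  tree <- toy_tree()
  expect_equal(rpd(tree, c("A", "B", "C")), 1)
  expect_equal(rpd(tree, c("A", "B")), 0.8)

  equal_tree <- tree
  equal_tree$edge.length <- rep(2, nrow(tree$edge))
  for (tips in all_tip_subsets(tree)) {
    expect_equal(rpd(equal_tree, tips), 1, tolerance = 1e-12)
  }
  scaled <- tree
  scaled$edge.length <- tree$edge.length * 17.3
  for (tips in all_tip_subsets(tree)) {
    expect_equal(rpd(scaled, tips), rpd(tree, tips), tolerance = 1e-12)
  }
})

test_that("exhaustive MPD null mean equals the pool mean pairwise distance", {
  # Each unordered pair is equally likely under uniform subset sampling, so
  # the expectation of MPD is the pool-wide mean pairwise distance for any k.
  for (seed in 1:3) {
    tree <- random_coal_tree(8, seed + 10)
    D <- patristic_matrix(tree)
    pool_mean <- mean(D[upper.tri(D)])
    for (k in 2:7) {
      s <- ses_metric(tree, tree$tip.label[1:k], "MPD",
                      null_spec(mode = "exhaustive"))
      expect_equal(s$null_mean, pool_mean, tolerance = 1e-12)
    }
  }
})

test_that("degenerate nulls give NA SES with a reason, not an error", {
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  s <- ses_metric(star, c("A", "B"), "MPD", null_spec(mode = "exhaustive"))
  expect_true(is.na(s$ses))
  expect_match(s$reason, "zero spread")

  tree <- random_coal_tree(6, 2)
  s2 <- ses_metric(tree, tree$tip.label, "PD", null_spec(mode = "exhaustive"))
  expect_true(is.na(s2$ses))
})

test_that("Monte Carlo SES converges to the exhaustive values", {
  tree <- random_coal_tree(7, 5)
  tips <- tree$tip.label[1:3]
  for (metric in c("PD", "MPD")) {
    ex <- ses_metric(tree, tips, metric, null_spec(mode = "exhaustive"))
    for (n in c(100, 10000)) {
      mc <- ses_metric(tree, tips, metric, null_spec(n, seed = 99))
      se <- ex$null_sd / sqrt(n)
      expect_lt(abs(mc$null_mean - ex$null_mean), 3 * se + 1e-12)
    }
    # exhaustive mode is seed-invariant
    ex2 <- ses_metric(tree, tips, metric,
                      null_spec(mode = "exhaustive", seed = 123))
    expect_identical(ex$ses, ex2$ses)
  }
})

test_that("compute_metric_table composes the per-metric oracles row by row", {
  cfg <- synthetic_config(n_tips = 20, grid_nx = 4, grid_ny = 4,
                          n_subcells = 4, seed = 3)
  w <- simulate_world(cfg)
  null <- null_spec(199, seed = 21)
  mt <- suppressWarnings(compute_metric_table(w$tree, w$assemblages,
                                              w$regions, null))
  expect_identical(colnames(mt),
                   c("region_id", "richness", "PD_raw", "PD", "MPD", "RPD",
                     "PD_ses", "MPD_ses"))
  asm <- split(w$assemblages$species, w$assemblages$region_id)
  area <- setNames(w$regions$area_km2, w$regions$region_id)
  for (i in seq_len(nrow(mt))) {
    rid <- mt$region_id[i]
    tips <- asm[[rid]]
    expect_equal(mt$richness[i], length(tips))
    expect_equal(mt$PD_raw[i], bf_pd(w$tree, tips), tolerance = 1e-10)
    expect_equal(mt$PD[i], bf_pd(w$tree, tips) / log10(area[[rid]]),
                 tolerance = 1e-10)
    expect_equal(mt$RPD[i], bf_rpd(w$tree, tips), tolerance = 1e-10)
    if (length(tips) >= 2) {
      expect_equal(mt$MPD[i], bf_mpd(w$tree, tips), tolerance = 1e-10)
    } else {
      expect_true(is.na(mt$MPD[i]))
    }
  }
  # determinism given the seed
  mt2 <- suppressWarnings(compute_metric_table(w$tree, w$assemblages,
                                               w$regions, null))
  expect_identical(mt, mt2)
})

test_that("a region holding the whole pool gives PD_raw = total length, RPD = 1", {
  tree <- random_coal_tree(8, 9)
  asm <- data.frame(region_id = "all", species = tree$tip.label)
  regions <- data.frame(region_id = "all", area_km2 = 1e4)
  mt <- compute_metric_table(tree, asm, regions, null_spec(99, seed = 5))
  expect_equal(mt$PD_raw, total_length(tree))
  expect_equal(mt$RPD, 1)
  expect_true(is.na(mt$PD_ses))  # whole-pool null has zero spread
})

test_that("unmatched species are dropped and identical regions differ only by area", {
  tree <- toy_tree()
  asm <- data.frame(region_id = c("r1", "r1", "r1", "r2", "r2"),
                    species = c("A", "B", "ghost", "A", "B"))
  regions <- data.frame(region_id = c("r1", "r2"), area_km2 = c(1e3, 1e5))
  expect_message(
    mt <- compute_metric_table(tree, asm, regions, null_spec(99, seed = 1)),
    "dropped")
  expect_equal(mt$MPD[1], mt$MPD[2])
  expect_equal(mt$RPD[1], mt$RPD[2])
  expect_equal(mt$PD[1] / mt$PD[2], log10(1e5) / log10(1e3))
})
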