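# Independent brute-force oracles. These deliberately avoid the package's
# own traversal code: paths come from ape::nodepath, distances from
# ape::cophenetic.phylo.

# Root-inclusive Faith PD: union of edges on every root-to-tip path.
bf_pd <- function(tree, tips) {
  root <- ape::Ntip(tree) + 1L
  edges <- character(0)
  for (tip in tips) {
    path <- ape::nodepath(tree, root, match(tip, tree$tip.label))
    edges <- union(edges, paste(path[-length(path)], path[-1]))
  }
  keys <- paste(tree$edge[, 1], tree$edge[, 2])
  sum(tree$edge.length[keys %in% edges])
}

bf_mpd <- function(tree, tips) {
  D <- ape::cophenetic.phylo(tree)[tips, tips]
  mean(D[upper.tri(D)])
}

bf_rpd <- function(tree, tips) {
  unit <- tree
  unit$edge.length <- rep(1, nrow(tree$edge))
  (bf_pd(tree, tips) / sum(tree$edge.length)) /
    (bf_pd(unit, tips) / nrow(tree$edge))
}

# All non-empty tip subsets of a tree (for exhaustive oracle sweeps).
all_tip_subsets <- function(tree, min_size = 1) {
  n <- ape::Ntip(tree)
  out <- list()
  for (k in seq(min_size, n)) {
    cmb <- utils::combn(tree$tip.label, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# Small random ultrametric tree with reproducible labels.
random_coal_tree <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n)
  tree$tip.label <- paste0("t", seq_len(n))
  tree
}

# Small seeded world used by several integration tests.
small_world_config <- function(seed = 11) {
  synthetic_config(n_tips = 60, grid_nx = 8, grid_ny = 8, n_subcells = 9,
                   seed = seed)
}
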