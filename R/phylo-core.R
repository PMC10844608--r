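#' Read a rooted Newick tree
#'
#' Parses a single rooted Newick string into an `ape::phylo` object, after
#' validating that every edge carries a finite, non-negative branch length and
#' that tip labels are unique. Parse failures report the character position of
#' the first structural problem.
#'
#' @param text A Newick string (terminated by `;`).
#' @return A rooted `phylo` object with `edge.length` set.
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  .check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse failure: no tree found", call. = FALSE)
  validate_phylo(tree)
  tree
}

# Structural scan so parse errors can name a character position.
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse failure at character ", i, ": unmatched ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse failure at character ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse failure at character ", nchar(text),
         ": missing terminating ';'", call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate the invariants a phylogeny must satisfy
#'
#' Checks a `phylo` object for: one root, unique tip labels, and finite,
#' non-negative branch lengths on every edge with positive total length.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly, if valid; otherwise an error.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object", call. = FALSE)
  if (is.null(tree$edge.length)) {
    stop("missing branch length: tree has no edge lengths", call. = FALSE)
  }
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("missing branch length: one or more edges lack a finite length", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch length", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (sum(tree$edge.length) <= 0) stop("total tree length must be > 0", call. = FALSE)
  invisible(tree)
}

#' Write a tree as a normalized Newick string
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @return A single Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

#' Total branch length of a tree
#' @param tree A `phylo` object.
#' @return Sum of all branch lengths.
#' @export
total_length <- function(tree) sum(tree$edge.length)

#' Patristic distance between two tips
#'
#' Branch-length distance along the path connecting two tips through their
#' most recent common ancestor.
#'
#' @param tree A `phylo` object with edge lengths.
#' @param a,b Tip labels.
#' @return A single non-negative number; 0 when `a == b`.
#' @export
patristic_distance <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  if (is.na(ia)) stop("unknown tip label: ", a, call. = FALSE)
  if (is.na(ib)) stop("unknown tip label: ", b, call. = FALSE)
  if (ia == ib) return(0)
  depths <- ape::node.depth.edgelength(tree)
  mrca <- ape::getMRCA(tree, c(ia, ib))
  depths[ia] + depths[ib] - 2 * depths[mrca]
}

#' Patristic distance matrix for all tips
#' @param tree A `phylo` object.
#' @return A symmetric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  stats::cophenetic(tree)
}

# Age of each node above the present, assuming the tree is ultrametric:
# age = (max root-to-tip depth) - (root-to-node depth).
node_ages <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  max(depths[seq_len(ape::Ntip(tree))]) - depths
}

#' Test whether a tree is ultrametric within a relative tolerance
#'
#' @param tree A `phylo` object.
#' @param rel_tol Tolerance relative to tree depth (default 1e-6).
#' @return Logical scalar.
#' @export
is_ultrametric_tol <- function(tree, rel_tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(depths)
  if (depth <= 0) return(FALSE)
  (max(depths) - min(depths)) <= rel_tol * depth
}

#' Parse genus names from tip labels
#'
#' The genus is the first whitespace- or underscore-delimited token of a
#' label, the convention used by megatree tip labels ("Genus_species").
#'
#' @param labels Character vector of tip labels.
#' @return Character vector of genus names.
#' @export
genus_of <- function(labels) {
  vapply(strsplit(labels, "[ _]+"), `[[`, character(1), 1L)
}

#' Graft species onto a backbone megatree at genus nodes
#'
#' Attaches each new species whose genus occurs among the backbone tips at the
#' most basal node of that genus: the MRCA of its congeneric tips, or, for a
#' monotypic genus, the parent node of its single tip. The pendant branch
#' length equals the attachment node's age, so ultrametricity is preserved.
#' Species whose genus is absent from the backbone are skipped and reported.
#'
#' @param backbone An ultrametric `phylo` object (relative tolerance `1e-6`
#'   of tree depth).
#' @param new_species Character vector of "Genus_species" labels to attach.
#' @param genus_of_tip Optional named character vector mapping every backbone
#'   tip label to its genus; parsed from labels when `NULL`.
#' @return A list with `tree` (the grafted phylogeny) and `report` (a tibble
#'   with columns `species`, `action` in `{attached, skipped}`, and
#'   `attachment_node`, the node id at attachment time, `NA` for skipped).
#' @export
graft_species <- function(backbone, new_species, genus_of_tip = NULL) {
  validate_phylo(backbone)
  if (!is_ultrametric_tol(backbone)) {
    stop("backbone is not ultrametric within tolerance", call. = FALSE)
  }
  if (anyDuplicated(new_species)) {
    stop("duplicate new species labels", call. = FALSE)
  }
  if (any(new_species %in% backbone$tip.label)) {
    stop("new species already present in backbone: ",
         paste(intersect(new_species, backbone$tip.label), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(genus_of_tip)) {
    genus_of_tip <- stats::setNames(genus_of(backbone$tip.label), backbone$tip.label)
  }
  if (!all(backbone$tip.label %in% names(genus_of_tip))) {
    stop("genus mapping does not cover all backbone tips", call. = FALSE)
  }

  tree <- backbone
  genus_map <- genus_of_tip
  report <- vector("list", length(new_species))
  for (i in seq_along(new_species)) {
    sp <- new_species[i]
    gen <- genus_of(sp)
    congeners <- names(genus_map)[genus_map == gen]
    congeners <- intersect(congeners, tree$tip.label)
    if (length(congeners) == 0L) {
      report[[i]] <- tibble::tibble(species = sp, action = "skipped",
                                    attachment_node = NA_integer_)
      next
    }
    tip_idx <- match(congeners, tree$tip.label)
    if (length(tip_idx) >= 2L) {
      node <- ape::getMRCA(tree, tip_idx)
    } else {
      node <- tree$edge[tree$edge[, 2] == tip_idx, 1]
    }
    age <- node_ages(tree)[node]
    tree <- phytools::bind.tip(tree, tip.label = sp, edge.length = age,
                               where = node, position = 0)
    genus_map <- c(genus_map, stats::setNames(gen, sp))
    report[[i]] <- tibble::tibble(species = sp, action = "attached",
                                  attachment_node = as.integer(node))
  }
  list(tree = tree, report = dplyr::bind_rows(report))
}
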