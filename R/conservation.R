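#' Read a weighted species tree from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that enforces the invariants the
#' conservation score relies on: every edge carries a branch length, tip
#' labels are unique, and the total branch length is positive.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree with branch lengths.
#' @export
read_species_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("read_species_tree(): could not parse Newick in ", path)
  validate_species_tree(tree)
  tree
}

#' @rdname read_species_tree
#' @param tree An [ape::phylo] tree.
#' @export
write_species_tree <- function(tree, path) {
  validate_species_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("expected an ape 'phylo' tree")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    bad <- if (is.null(tree$edge.length)) "all" else which(is.na(tree$edge.length))
    stop("species tree is missing branch lengths (edge ",
         paste(bad, collapse = ", "), ")")
  }
  if (any(tree$edge.length < 0)) stop("species tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (sum(tree$edge.length) <= 0) stop("species tree has zero total branch length")
  invisible(tree)
}

# Logical matrix (n_tips x n_edges): does tip t lie below edge j
# (i.e. in the subtree hanging off the child end of edge j)?
# Works for rooted and unrooted (basal multifurcation) trees.
edge_tip_matrix <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  # accumulate tip sets per node in postorder (children before parents),
  # then read off the child-end set per edge
  tip_sets <- matrix(FALSE, nrow = n_node, ncol = n_tip)
  tip_sets[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  for (j in ape::postorder(tree)) {
    parent <- tree$edge[j, 1L]
    child <- tree$edge[j, 2L]
    tip_sets[parent, ] <- tip_sets[parent, ] | tip_sets[child, ]
  }
  m <- t(tip_sets[tree$edge[, 2L], , drop = FALSE])
  rownames(m) <- tree$tip.label
  m
}

#' Edges of the minimal subtree spanning a set of tips
#'
#' Returns the edge indices (rows of `tree$edge`) of the minimal connected
#' (Steiner) subtree of the unrooted topology that spans `retained_tips`.
#' An edge belongs to the spanning subtree exactly when removing it separates
#' at least one retained tip from another, i.e. when both sides of the split
#' it induces contain a retained tip. The path from the subtree towards the
#' root is therefore *not* included, and a single retained tip yields an
#' empty edge set.
#'
#' @param tree An [ape::phylo] tree with branch lengths.
#' @param retained_tips Character vector of tip labels.
#' @return Integer vector of edge indices into `tree$edge`.
#' @export
pruned_subtree_edges <- function(tree, retained_tips) {
  validate_species_tree(tree)
  retained_tips <- unique(retained_tips)
  unknown <- setdiff(retained_tips, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("unknown species label(s): ", paste(unknown, collapse = ", "))
  }
  m <- edge_tip_matrix(tree)
  r <- tree$tip.label %in% retained_tips
  below <- as.vector(crossprod(m, r))
  which(below >= 1 & (sum(r) - below) >= 1)
}

#' Phylogenetic tree-based conservation score
#'
#' For each protein, the species in which a homolog exists (the reference
#' species always included) define a pruned subtree of the weighted species
#' tree: the minimal unrooted subtree connecting those tips. The conservation
#' score is the total branch length of that subtree divided by the total
#' branch length of the full tree, so it lies in \eqn{[0, 1]}: 0 for a
#' protein found only in the reference species, 1 for a protein found in all
#' species. The score grows with both the number of species retained and the
#' evolutionary distance separating them.
#'
#' @param homology A data frame with columns `protein_id` and `species`;
#'   `species` is either a list-column of character vectors or a single
#'   comma-separated string per protein. The reference species is added to
#'   every protein's set if absent.
#' @param tree An [ape::phylo] species tree with branch lengths; every species
#'   named in `homology` must be a tip. Extra tips never queried by the
#'   homology table are an error: the loader enforces tree/table consistency.
#' @param reference Tip label of the reference species (default
#'   `"Homo_sapiens"`).
#' @param check_universe If `TRUE` (default), require every tree tip other
#'   than the reference to appear somewhere in the homology universe.
#' @return A tibble with columns `protein_id`, `score`, `subtree_length`,
#'   `tree_length`.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,Homo_sapiens:1):1);")
#' hom <- tibble::tibble(protein_id = c("p1", "p2"),
#'                       species = c("A,B,C", "C"))
#' conservation_score(hom, tree, check_universe = FALSE)
#' @export
conservation_score <- function(homology, tree, reference = "Homo_sapiens",
                               check_universe = TRUE) {
  validate_species_tree(tree)
  if (!reference %in% tree$tip.label) {
    stop("reference species '", reference, "' is not a tip of the tree")
  }
  species_sets <- homology_species_sets(homology)
  all_species <- unique(unlist(species_sets, use.names = FALSE))
  unknown <- setdiff(all_species, tree$tip.label)
  if (length(unknown) > 0L) {
    stop("homology table names species absent from the tree: ",
         paste(unknown, collapse = ", "))
  }
  if (check_universe) {
    unused <- setdiff(tree$tip.label, c(all_species, reference))
    if (length(unused) > 0L) {
      stop("tree tips never queried by the homology table: ",
           paste(unused, collapse = ", "),
           " (prune the tree or pass check_universe = FALSE)")
    }
  }

  m <- edge_tip_matrix(tree)              # tips x edges
  w <- tree$edge.length
  tree_length <- sum(w)

  # tips x proteins retention indicator, reference always retained
  tip_idx <- stats::setNames(seq_along(tree$tip.label), tree$tip.label)
  n_prot <- length(species_sets)
  ret <- matrix(FALSE, nrow = length(tip_idx), ncol = n_prot)
  for (i in seq_len(n_prot)) {
    ret[tip_idx[unique(c(species_sets[[i]], reference))], i] <- TRUE
  }
  n_ret <- colSums(ret)
  below <- crossprod(m, ret)              # edges x proteins retained-below counts
  in_subtree <- below >= 1 & sweep(-below, 2, n_ret, `+`) >= 1
  subtree_length <- as.vector(crossprod(in_subtree, w))

  tibble::tibble(
    protein_id = names(species_sets),
    score = subtree_length / tree_length,
    subtree_length = subtree_length,
    tree_length = tree_length
  )
}

# Normalize the two accepted homology encodings to a named list of
# character vectors (protein_id -> species labels).
homology_species_sets <- function(homology) {
  stopifnot(is.data.frame(homology),
            all(c("protein_id", "species") %in% names(homology)))
  if (anyDuplicated(homology$protein_id)) {
    stop("duplicate protein_id rows in homology table")
  }
  sets <- if (is.list(homology$species)) {
    homology$species
  } else {
    strsplit(as.character(homology$species), ",", fixed = TRUE)
  }
  sets <- lapply(sets, function(s) {
    s <- trimws(s[!is.na(s)])
    s[nzchar(s)]
  })
  names(sets) <- homology$protein_id
  sets
}
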