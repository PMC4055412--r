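# Independent oracles and tiny fixture builders shared across test files.

# Brute-force Steiner subtree: union of the edges on every pairwise
# tip-to-tip path, found via ape::nodepath. Independent of the package's
# split-based computation.
steiner_edges_oracle <- function(tree, retained_tips) {
  idx <- match(retained_tips, tree$tip.label)
  stopifnot(!anyNA(idx))
  if (length(idx) < 2) return(integer(0))
  edges <- integer(0)
  for (i in seq_len(length(idx) - 1)) {
    for (j in seq(i + 1, length(idx))) {
      np <- ape::nodepath(tree, idx[i], idx[j])
      for (k in seq_len(length(np) - 1)) {
        e <- which((tree$edge[, 1] == np[k] & tree$edge[, 2] == np[k + 1]) |
                     (tree$edge[, 1] == np[k + 1] & tree$edge[, 2] == np[k]))
        edges <- c(edges, e)
      }
    }
  }
  sort(unique(edges))
}

# Wide intensity tibble from a plain matrix with "<line>.<rep>" columns.
intensity_tibble <- function(values, lines, reps = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("P%03d", seq_len(nrow(values)))
  if (is.null(reps)) {
    reps <- stats::ave(seq_along(lines), lines, FUN = seq_along)
  }
  colnames(values) <- paste(lines, reps, sep = ".")
  dplyr::bind_cols(tibble::tibble(protein_id = ids),
                   tibble::as_tibble(values))
}

# iid standard-normal intensity tibble (already on "standardized" scale).
null_intensity_matrix <- function(n_proteins, n_lines, n_reps, seed) {
  withr::with_seed(seed, {
    lines <- rep(sprintf("L%02d", seq_len(n_lines)), each = n_reps)
    reps <- rep(seq_len(n_reps), times = n_lines)
    intensity_tibble(matrix(stats::rnorm(n_proteins * n_lines * n_reps),
                            nrow = n_proteins),
                     lines, reps)
  })
}

# random species tree with positive branch lengths for property tests
random_weighted_tree <- function(n_tips, seed) {
  withr::with_seed(seed, {
    ape::rtree(n_tips, br = function(k) stats::runif(k, 0.05, 1))
  })
}

small_world <- function(n = 600, seed = 42, ...) {
  generate_world(world_config(n_proteins = n, seed = seed, ...))
}
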