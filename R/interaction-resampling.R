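PAIR_CATEGORIES <- c("PPI-IT", "PPI-TO", "PPI-W", "PPI-Rand", "Rand-IT")

#' Canonical undirected edge list
#'
#' Normalizes a two-column protein pair table to an undirected edge list:
#' endpoints ordered within each pair, duplicates removed, self-loops
#' rejected.
#'
#' @param edges Data frame whose first two columns are protein ids.
#' @return Tibble with columns `protein_a`, `protein_b` (`protein_a <
#'   protein_b`), deduplicated.
#' @export
as_edge_list <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (any(a == b)) stop("as_edge_list(): self-loops are not allowed")
  tibble::tibble(protein_a = pmin(a, b), protein_b = pmax(a, b)) |>
    dplyr::distinct()
}

edge_keys <- function(edges) paste(edges$protein_a, edges$protein_b, sep = "\r")

pair_keys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# proteins eligible for pair sampling: unique bow-tie layer and finite log F
eligible_proteins <- function(layers, features) {
  layers |>
    dplyr::filter(.data$layer %in% c("input", "transmission", "output")) |>
    dplyr::inner_join(dplyr::select(features, "protein_id", "log10_f"),
                      by = "protein_id") |>
    dplyr::filter(is.finite(.data$log10_f))
}

#' Sample protein pairs by layer category
#'
#' Draws `n` pairs uniformly from the eligible pairs of one of five
#' categories: interacting input-transmission pairs (`PPI-IT`), interacting
#' transmission-output pairs (`PPI-TO`), interacting pairs within one layer
#' (`PPI-W`), any interacting pair among layer-annotated proteins
#' (`PPI-Rand`), and non-interacting input-transmission pairs (`Rand-IT`,
#' rejection-sampled against the edge set). Only proteins with a unique
#' bow-tie layer and a finite log F are eligible. Sampling is without
#' replacement when at least `n` eligible pairs exist, with replacement
#' otherwise (recorded in the result).
#'
#' @param edges Edge list (see [as_edge_list()]; coerced if needed).
#' @param layers Layer annotation ([annotate_layers()] output).
#' @param features Feature table with `protein_id`, `log10_f`.
#' @param category One of `"PPI-IT"`, `"PPI-TO"`, `"PPI-W"`, `"PPI-Rand"`,
#'   `"Rand-IT"`.
#' @param n Number of pairs (default 1000).
#' @param seed Integer seed; the draw is a pure function of it.
#' @param replace Force sampling with/without replacement; default `NULL`
#'   chooses without replacement iff >= `n` eligible pairs exist.
#' @return A `pair_sample`: tibble with `protein_a`, `protein_b`, `log_f_a`,
#'   `log_f_b`, and attributes `category`, `seed`, `replace`.
#' @export
sample_pairs <- function(edges, layers, features, category, n = 1000, seed,
                         replace = NULL) {
  category <- match.arg(category, PAIR_CATEGORIES)
  stopifnot(n >= 1)
  edges <- as_edge_list(edges)
  elig <- eligible_proteins(layers, features)
  layer_of <- stats::setNames(elig$layer, elig$protein_id)
  logf_of <- stats::setNames(elig$log10_f, elig$protein_id)

  ann_edges <- edges |>
    dplyr::filter(.data$protein_a %in% elig$protein_id,
                  .data$protein_b %in% elig$protein_id) |>
    dplyr::mutate(layer_a = unname(layer_of[.data$protein_a]),
                  layer_b = unname(layer_of[.data$protein_b]))

  cross_edges <- function(l1, l2) {
    ann_edges |>
      dplyr::filter((.data$layer_a == l1 & .data$layer_b == l2) |
                      (.data$layer_a == l2 & .data$layer_b == l1))
  }

  withr::with_seed(seed, {
    if (category == "Rand-IT") {
      inputs <- elig$protein_id[elig$layer == "input"]
      transm <- elig$protein_id[elig$layer == "transmission"]
      if (length(inputs) == 0L || length(transm) == 0L) {
        stop("sample_pairs(): no eligible proteins for category Rand-IT")
      }
      keys <- edge_keys(edges)
      got_a <- character(0)
      got_b <- character(0)
      attempts <- 0L
      while (length(got_a) < n) {
        need <- n - length(got_a)
        attempts <- attempts + need
        if (attempts > 10L * n) {
          stop("sample_pairs(): rejection-sampling cap reached for Rand-IT")
        }
        ca <- sample(inputs, need, replace = TRUE)
        cb <- sample(transm, need, replace = TRUE)
        ok <- !(pair_keys(ca, cb) %in% keys)
        got_a <- c(got_a, ca[ok])
        got_b <- c(got_b, cb[ok])
      }
      pool <- tibble::tibble(protein_a = got_a, protein_b = got_b)
      was_replace <- TRUE
    } else {
      pool <- switch(category,
        "PPI-IT" = cross_edges("input", "transmission"),
        "PPI-TO" = cross_edges("transmission", "output"),
        "PPI-W" = dplyr::filter(ann_edges, .data$layer_a == .data$layer_b),
        "PPI-Rand" = ann_edges
      )
      if (nrow(pool) == 0L) {
        stop("sample_pairs(): no eligible pairs for category ", category)
      }
      was_replace <- if (is.null(replace)) nrow(pool) < n else replace
      if (was_replace && nrow(pool) < n) {
        message("sample_pairs(): ", category, " has ", nrow(pool),
                " eligible pairs < n = ", n, "; sampling with replacement")
      }
      pool <- pool[sample.int(nrow(pool), n, replace = was_replace), ,
                   drop = FALSE]
      # orient cross-layer pairs (first-named layer in column a) so that
      # permutation nulls can shuffle column b without breaking the
      # layer constraint
      first_layer <- switch(category, "PPI-IT" = "input",
                            "PPI-TO" = "transmission", NULL)
      if (!is.null(first_layer)) {
        flip <- unname(layer_of[pool$protein_a]) != first_layer
        tmp <- pool$protein_a[flip]
        pool$protein_a[flip] <- pool$protein_b[flip]
        pool$protein_b[flip] <- tmp
      }
    }
    out <- tibble::tibble(
      protein_a = pool$protein_a,
      protein_b = pool$protein_b,
      log_f_a = unname(logf_of[pool$protein_a]),
      log_f_b = unname(logf_of[pool$protein_b])
    )
  })
  structure(out, category = category, seed = seed, replace = was_replace,
            class = c("pair_sample", class(out)))
}

#' Absolute variability difference within sampled pairs
#'
#' @param sample A `pair_sample`.
#' @return Numeric vector of `|log F_a - log F_b|`, one value per pair.
#' @export
abs_variability_diff <- function(sample) {
  stopifnot(inherits(sample, "pair_sample"))
  abs(sample$log_f_a - sample$log_f_b)
}

#' Permutation null: shuffle the transmission endpoints of PPI-IT pairs
#'
#' Keeps the input-side endpoints in place and randomly permutes the
#' transmission-side endpoints among pairs, breaking any pairing between
#' partner variabilities while preserving both endpoint multisets and the
#' layer constraint. The permuted pairs need not be edges.
#'
#' @param sample A `pair_sample` of category `"PPI-IT"` with >= 2 pairs.
#' @param seed Integer seed.
#' @return A `pair_sample` of category `"Perm-IT"`.
#' @export
permute_links <- function(sample, seed) {
  stopifnot(inherits(sample, "pair_sample"))
  if (!identical(attr(sample, "category"), "PPI-IT")) {
    stop("permute_links(): input must be a PPI-IT sample")
  }
  n <- nrow(sample)
  if (n < 2) stop("permute_links(): need at least 2 pairs")
  # PPI-IT samples are oriented input-in-column-a, so shuffling column b
  # moves only transmission endpoints
  out <- withr::with_seed(seed, {
    perm <- sample.int(n)
    tibble::tibble(
      protein_a = sample$protein_a,
      protein_b = sample$protein_b[perm],
      log_f_a = sample$log_f_a,
      log_f_b = sample$log_f_b[perm]
    )
  })
  structure(out, category = "Perm-IT", seed = seed,
            replace = attr(sample, "replace"),
            class = c("pair_sample", class(out)))
}

#' Compare two |variability difference| distributions
#'
#' Two-sided rank-sum test between the absolute log-F difference
#' distributions of two pair samples (or raw numeric vectors).
#'
#' @param dist_a,dist_b `pair_sample` objects or numeric vectors of
#'   differences.
#' @param alpha Significance threshold (default 0.01).
#' @return A `bowtie_comparison`; `direction` refers to `dist_a`.
#' @export
compare_pair_distributions <- function(dist_a, dist_b, alpha = 0.01) {
  lab <- function(d, fallback) {
    if (inherits(d, "pair_sample")) attr(d, "category") else fallback
  }
  to_num <- function(d) if (inherits(d, "pair_sample")) abs_variability_diff(d) else d
  rank_sum_test(to_num(dist_a), to_num(dist_b), alpha = alpha,
                label_a = lab(dist_a, "dist_a"), label_b = lab(dist_b, "dist_b"))
}
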