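MUTATION_CLASSES <- c("somatic", "germline", "snp")

validate_mutation_counts <- function(counts) {
  need <- c("protein_id", "n_somatic", "n_germline", "n_snp")
  stopifnot(is.data.frame(counts), all(need %in% names(counts)))
  vals <- as.matrix(counts[c("n_somatic", "n_germline", "n_snp")])
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals))) {
    stop("mutation counts must be non-negative integers")
  }
  invisible(counts)
}

#' Compare a feature between somatic- and germline-mutated proteins
#'
#' Two-sided rank-sum test of the named feature between proteins carrying at
#' least one somatic mutation and proteins carrying at least one germline
#' disease mutation. Proteins carrying both kinds belong to both groups.
#'
#' @param features Feature table with `protein_id` and the feature column.
#' @param counts Mutation count table (`protein_id`, `n_somatic`,
#'   `n_germline`, `n_snp`).
#' @param feature Feature column name (e.g. `"conservation"`, `"log10_f"`,
#'   `"mean_abundance"`).
#' @param alpha Significance threshold (default 0.01).
#' @return A `bowtie_comparison` (`direction` is the somatic group relative
#'   to the germline group).
#' @export
mutation_class_comparison <- function(features, counts, feature,
                                      alpha = 0.01) {
  validate_mutation_counts(counts)
  stopifnot(feature %in% names(features))
  dat <- dplyr::inner_join(features, counts, by = "protein_id")
  vals <- dat[[feature]]
  ok <- is.finite(vals)
  som <- vals[ok & dat$n_somatic > 0]
  ger <- vals[ok & dat$n_germline > 0]
  if (length(som) == 0L || length(ger) == 0L) {
    stop("mutation_class_comparison(): empty somatic or germline group")
  }
  rank_sum_test(som, ger, alpha = alpha,
                label_a = "somatic", label_b = "germline")
}

#' Binned mutation-rate profile along a protein feature
#'
#' Splits proteins into `k` near-equal rank-based bins of the named feature
#' and reports, per bin and per mutation class (somatic, germline, SNP), the
#' mean number of mutations per protein. Proteins with zero mutations in a
#' class contribute zeros to that class's bin mean, so the identity
#' `sum(bin_n * bin_mean) == total class count` holds exactly. The optional
#' normalization divides each class's profile by its overall mean mutation
#' count so classes with very different totals are comparable on one axis.
#'
#' @param features Feature table with `protein_id` and the feature column.
#' @param counts Mutation count table.
#' @param feature Feature column to bin on.
#' @param k Number of quantile bins (default 5).
#' @param normalize Divide each class profile by the class's overall mean
#'   (default `FALSE`).
#' @return A `binned_profile`: tibble with `bin`, `lo`, `hi`, `n_proteins`,
#'   `class`, `mean_count` (long format), plus attributes `feature`,
#'   `normalize`.
#' @export
binned_mutation_profile <- function(features, counts, feature, k = 5,
                                    normalize = FALSE) {
  validate_mutation_counts(counts)
  stopifnot(feature %in% names(features))
  dat <- dplyr::inner_join(features, counts, by = "protein_id")
  dat <- dat[is.finite(dat[[feature]]), , drop = FALSE]
  bins <- quantile_bin(dat[[feature]], k)
  edges <- attr(bins, "edges")

  prof <- tibble::tibble(
    bin = bins,
    somatic = dat$n_somatic,
    germline = dat$n_germline,
    snp = dat$n_snp
  ) |>
    tidyr::pivot_longer(dplyr::all_of(MUTATION_CLASSES),
                        names_to = "class", values_to = "count") |>
    dplyr::group_by(.data$bin, .data$class) |>
    dplyr::summarise(n_proteins = dplyr::n(),
                     mean_count = mean(.data$count), .groups = "drop")

  if (normalize) {
    prof <- prof |>
      dplyr::group_by(.data$class) |>
      dplyr::mutate(mean_count = .data$mean_count /
                      (sum(.data$n_proteins * .data$mean_count) /
                         sum(.data$n_proteins))) |>
      dplyr::ungroup()
  }

  out <- edges |>
    dplyr::select("bin", "lo", "hi") |>
    dplyr::inner_join(prof, by = "bin") |>
    dplyr::arrange(.data$bin, .data$class)
  structure(out, feature = feature, normalize = normalize,
            class = c("binned_profile", class(out)))
}

#' @export
tidy.binned_profile <- function(x, ...) tibble::as_tibble(x)

#' Hypergeometric over-representation test with Bonferroni correction
#'
#' For each annotation term, tests whether the target set contains more term
#' members than expected under hypergeometric sampling from the background
#' (one-sided upper tail), then applies Bonferroni correction over the
#' number of tested terms. A generic stand-in for web-tool enrichment
#' reports; no EASE-style adjustment is applied.
#'
#' @param target_set Character vector of protein ids, a subset of
#'   `background`.
#' @param annotation_map Named list of character vectors (term -> protein
#'   set), or a data frame with columns `term`, `protein_id`. Every
#'   annotation set must lie within `background`.
#' @param background Character vector: the tested universe (non-empty).
#' @return Tibble sorted by corrected p: `term`, `overlap`, `term_size`,
#'   `target_size`, `background_size`, `p_raw`, `p_bonferroni`.
#' @export
enrichment_test <- function(target_set, annotation_map, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("enrichment_test(): empty background")
  target_set <- unique(target_set)
  if (!all(target_set %in% background)) {
    stop("enrichment_test(): target set is not a subset of the background")
  }
  if (is.data.frame(annotation_map)) {
    stopifnot(all(c("term", "protein_id") %in% names(annotation_map)))
    annotation_map <- split(annotation_map$protein_id, annotation_map$term)
  }
  annotation_map <- lapply(annotation_map, unique)
  if (!all(unlist(annotation_map) %in% background)) {
    stop("enrichment_test(): annotation set(s) extend beyond the background")
  }
  m <- length(annotation_map)
  n_bg <- length(background)
  n_t <- length(target_set)
  purrr::imap_dfr(annotation_map, function(set, term) {
    k <- length(set)
    q <- length(intersect(set, target_set))
    p <- stats::phyper(q - 1, k, n_bg - k, n_t, lower.tail = FALSE)
    tibble::tibble(term = term, overlap = q, term_size = k,
                   target_size = n_t, background_size = n_bg,
                   p_raw = p, p_bonferroni = min(1, p * m))
  }) |>
    dplyr::arrange(.data$p_bonferroni, .data$p_raw)
}
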