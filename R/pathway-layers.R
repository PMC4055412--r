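VALID_RAW_CLASSES <- c("receptor", "kinase", "phosphatase", "adaptor",
                       "gtpase_binding", "transcription_factor", "ligand",
                       "mediator", "cofactor", "none")

TRANSMISSION_CLASSES <- c("kinase", "phosphatase", "adaptor",
                          "gtpase_binding", "mediator", "cofactor")

validate_pathway_table <- function(pathway_table) {
  stopifnot(is.data.frame(pathway_table),
            all(c("protein_id", "pathway_id", "source", "raw_class") %in%
                  names(pathway_table)))
  bad <- setdiff(unique(pathway_table$raw_class), VALID_RAW_CLASSES)
  if (length(bad) > 0L) {
    stop("unknown raw_class value(s): ", paste(bad, collapse = ", "))
  }
  bad_src <- setdiff(unique(pathway_table$source), c("reactome", "signalink"))
  if (length(bad_src) > 0L) {
    stop("unknown source value(s): ", paste(bad_src, collapse = ", "))
  }
  invisible(pathway_table)
}

#' Assign each protein a unique functional class
#'
#' A protein keeps a functional class only when its annotations support a
#' single one: proteins whose rows name two or more distinct (non-`none`)
#' classes are marked `ambiguous` and excluded from all layer analyses;
#' proteins with only `none` rows are `none`. Pathway membership counts and
#' the exclusive (single-pathway) flag are tallied at the same time.
#'
#' @param pathway_table Data frame with columns `protein_id`, `pathway_id`,
#'   `source` (`"reactome"`/`"signalink"`), `raw_class` (one of receptor,
#'   kinase, phosphatase, adaptor, gtpase_binding, transcription_factor,
#'   ligand, mediator, cofactor, none).
#' @return Tibble with `protein_id`, `functional_class`, `pathway_count`,
#'   `exclusive`.
#' @export
assign_functional_class <- function(pathway_table) {
  validate_pathway_table(pathway_table)
  pathway_table |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      functional_class = {
        cl <- setdiff(unique(.data$raw_class), "none")
        if (length(cl) == 0L) "none" else if (length(cl) == 1L) cl else "ambiguous"
      },
      pathway_count = dplyr::n_distinct(.data$pathway_id),
      .groups = "drop"
    ) |>
    dplyr::mutate(exclusive = .data$pathway_count == 1L)
}

#' Pool functional classes into bow-tie layers
#'
#' Receptors form the input layer, transcription factors the output layer,
#' and kinases, phosphatases, adaptors, GTPase-binding proteins, mediators
#' and cofactors the transmission layer — mediators and cofactors only enter
#' when they are neither receptors nor transcription factors, which the
#' unique-class rule guarantees (a mediator also annotated as receptor is
#' `ambiguous` and unassigned). Ligands, `none` and ambiguous proteins stay
#' `unassigned`.
#'
#' @param classes Output of [assign_functional_class()].
#' @return The same tibble with a `layer` column in
#'   `{input, transmission, output, unassigned}`.
#' @export
pool_layers <- function(classes) {
  stopifnot("functional_class" %in% names(classes))
  classes |>
    dplyr::mutate(layer = dplyr::case_when(
      .data$functional_class == "receptor" ~ "input",
      .data$functional_class == "transcription_factor" ~ "output",
      .data$functional_class %in% TRANSMISSION_CLASSES ~ "transmission",
      TRUE ~ "unassigned"
    ))
}

#' @rdname pool_layers
#' @param pathway_table Raw pathway table; convenience composition
#'   `pool_layers(assign_functional_class(pathway_table))`.
#' @export
annotate_layers <- function(pathway_table) {
  pool_layers(assign_functional_class(pathway_table))
}

#' Compare a feature between a protein class and its complement
#'
#' Two-sided rank-sum test of the feature values of `members` against the
#' rest of `universe`, reporting the direction (class higher or lower than
#' its complement) when significant at `alpha`.
#'
#' @param features Feature table with `protein_id` and the feature column.
#' @param feature Name of the feature column (string).
#' @param members Protein ids of the class.
#' @param universe Protein ids of the comparison universe (default: all
#'   proteins in `features`). `members` must be a proper subset.
#' @param alpha Significance threshold (default 0.01).
#' @return A `bowtie_comparison`.
#' @export
class_feature_test <- function(features, feature, members,
                               universe = features$protein_id, alpha = 0.01) {
  stopifnot(feature %in% names(features))
  vals <- features[[feature]]
  names_ok <- features$protein_id %in% universe & is.finite(vals)
  in_class <- names_ok & features$protein_id %in% members
  out_class <- names_ok & !features$protein_id %in% members
  if (!any(in_class) || !any(out_class)) {
    stop("class_feature_test(): class or complement is empty within the universe")
  }
  rank_sum_test(vals[in_class], vals[out_class], alpha = alpha,
                label_a = "class", label_b = "complement")
}

#' Per-layer feature distributions and pairwise comparisons
#'
#' For each requested feature, summarises the distribution within each
#' bow-tie layer (n, median, IQR) and runs all pairwise rank-sum tests
#' between populated layers. Layers with fewer than two finite values are
#' excluded with a warning. Proteins lacking a feature value are dropped
#' per-test.
#'
#' @param features Feature table with `protein_id` and feature columns.
#' @param layers Layer annotation (output of [annotate_layers()]).
#' @param feature_cols Feature columns to analyse.
#' @param alpha Significance threshold (default 0.01).
#' @return An object of class `bowtie_layer_summary`: list with tibbles
#'   `summary` (feature, layer, n, median, iqr) and `comparisons`
#'   (feature, layer_a, layer_b, statistic, p_value, direction, ...), plus
#'   the merged per-protein data for plotting.
#' @export
layer_feature_summary <- function(features, layers,
                                  feature_cols = c("log10_f", "conservation",
                                                   "mean_abundance"),
                                  alpha = 0.01) {
  stopifnot(all(feature_cols %in% names(features)))
  dat <- features |>
    dplyr::inner_join(dplyr::select(layers, "protein_id", "layer"),
                      by = "protein_id") |>
    dplyr::filter(.data$layer != "unassigned")

  long <- dat |>
    tidyr::pivot_longer(dplyr::all_of(feature_cols),
                        names_to = "feature", values_to = "value") |>
    dplyr::filter(is.finite(.data$value))

  summary <- long |>
    dplyr::group_by(.data$feature, .data$layer) |>
    dplyr::summarise(n = dplyr::n(),
                     median = stats::median(.data$value),
                     iqr = stats::IQR(.data$value), .groups = "drop")

  comparisons <- long |>
    dplyr::group_by(.data$feature) |>
    dplyr::group_modify(function(d, key) {
      lay <- d |>
        dplyr::count(.data$layer) |>
        dplyr::filter(.data$n >= 2) |>
        dplyr::pull(.data$layer)
      dropped <- setdiff(unique(d$layer), lay)
      if (length(dropped) > 0L) {
        warning("layer_feature_summary(): layer(s) with < 2 values excluded: ",
                paste(dropped, collapse = ", "))
      }
      if (length(lay) < 2L) return(tibble::tibble())
      pairs <- utils::combn(sort(lay), 2, simplify = FALSE)
      purrr::map_dfr(pairs, function(p) {
        cmp <- rank_sum_test(d$value[d$layer == p[1]], d$value[d$layer == p[2]],
                             alpha = alpha, label_a = p[1], label_b = p[2])
        dplyr::rename(tidy(cmp), layer_a = "group_a", layer_b = "group_b")
      })
    }) |>
    dplyr::ungroup()

  structure(list(summary = summary, comparisons = comparisons, data = long),
            class = "bowtie_layer_summary")
}

#' @export
print.bowtie_layer_summary <- function(x, ...) {
  cat("Bow-tie layer feature summary\n\nPer-layer distributions:\n")
  print(x$summary, n = Inf)
  cat("\nPairwise rank-sum comparisons:\n")
  print(x$comparisons, n = Inf)
  invisible(x)
}

#' @export
tidy.bowtie_layer_summary <- function(x, ...) x$comparisons

#' @export
glance.bowtie_layer_summary <- function(x, ...) {
  tibble::tibble(n_features = dplyr::n_distinct(x$summary$feature),
                 n_layers = dplyr::n_distinct(x$summary$layer),
                 n_comparisons = nrow(x$comparisons),
                 n_significant = sum(x$comparisons$direction != "none"))
}

#' Exclusive vs multi-pathway proteins
#'
#' Partitions proteins into those annotated to exactly one pathway
#' (exclusive) and those re-used across several, compares the three protein
#' features between the partitions, and reports the per-class
#' overrepresentation among multi-pathway proteins as a fold ratio:
#' observed class count in the multiple set over the count expected from the
#' class's overall frequency.
#'
#' @param pathway_table Raw pathway table.
#' @param features Feature table with the columns in `feature_cols`.
#' @param feature_cols Features to compare (default conservation, log F,
#'   mean abundance).
#' @param alpha Significance threshold.
#' @return List with `exclusive` and `multiple` id vectors, a `comparisons`
#'   tibble (empty when either side is, with a message), and a `class_fold`
#'   tibble (functional_class, observed, expected, fold).
#' @export
split_exclusive_multiple <- function(pathway_table, features,
                                     feature_cols = c("conservation", "log10_f",
                                                      "mean_abundance"),
                                     alpha = 0.01) {
  ann <- assign_functional_class(pathway_table)
  exclusive <- ann$protein_id[ann$exclusive]
  multiple <- ann$protein_id[!ann$exclusive]

  comparisons <- tibble::tibble()
  if (length(exclusive) > 0L && length(multiple) > 0L) {
    comparisons <- purrr::map_dfr(
      intersect(feature_cols, names(features)),
      function(fc) {
        vals <- features[[fc]]
        ok <- is.finite(vals)
        a <- vals[ok & features$protein_id %in% exclusive]
        b <- vals[ok & features$protein_id %in% multiple]
        if (length(a) == 0L || length(b) == 0L) return(tibble::tibble())
        cmp <- rank_sum_test(a, b, alpha = alpha,
                             label_a = "exclusive", label_b = "multiple")
        dplyr::mutate(tidy(cmp), feature = fc, .before = 1)
      }
    )
  } else {
    message("split_exclusive_multiple(): one partition is empty; comparisons skipped")
  }

  class_fold <- ann |>
    dplyr::filter(!.data$functional_class %in% c("none", "ambiguous")) |>
    dplyr::mutate(multiple = !.data$exclusive) |>
    dplyr::group_by(.data$functional_class) |>
    dplyr::summarise(observed = sum(.data$multiple),
                     class_size = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      set_size = sum(.data$observed),
      universe = sum(.data$class_size),
      expected = .data$class_size / .data$universe * .data$set_size,
      fold = .data$observed / .data$expected
    ) |>
    dplyr::select("functional_class", "observed", "expected", "fold")

  list(exclusive = exclusive, multiple = multiple,
       comparisons = comparisons, class_fold = class_fold)
}

#' Rank-based quantile bins
#'
#' Assigns values to `k` bins of near-equal occupancy by rank; all members of
#' a tie group share the bin of their minimum rank (ties go to the lower
#' bin), so bin sizes differ by at most the largest tie-group size.
#'
#' @param values Numeric vector without missing values.
#' @param k Number of bins (>= 2); requires at least `k` distinct values.
#' @return Integer vector of bin indices in `1:k`, with attribute `edges`
#'   (a tibble of per-bin value ranges and counts).
#' @examples
#' quantile_bin(1:10, 5)
#' @export
quantile_bin <- function(values, k = 5) {
  stopifnot(k >= 2, !anyNA(values))
  if (length(unique(values)) < k) {
    stop("quantile_bin(): fewer than k distinct values")
  }
  n <- length(values)
  r <- rank(values, ties.method = "min")
  bins <- ceiling(r * k / n)
  bins[bins < 1L] <- 1L
  edges <- tibble::tibble(bin = bins, value = values) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(lo = min(.data$value), hi = max(.data$value),
                     n = dplyr::n(), .groups = "drop")
  attr(bins, "edges") <- edges
  bins
}
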