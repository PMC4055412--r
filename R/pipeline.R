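#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one set of inputs: per-protein features
#' (detection filter, per-sample standardization, mean abundance, F value),
#' conservation scores, bow-tie layer annotation with layer and
#' exclusive-vs-multiple comparisons, feature correlations, PPI pair
#' resampling with the permutation and non-interacting nulls, and mutation
#' class comparisons with binned profiles plus a pathway-term enrichment
#' scan of the conservation extremes. All randomness (pair sampling) derives
#' from `seed` through independent per-stage streams, so the same inputs and
#' seed give an identical report.
#'
#' @param world A `bowtie_world` from [generate_world()] or a list of the
#'   six tables as returned by [read_world()].
#' @param alpha Significance threshold for direction calls (default 0.01).
#' @param n_pairs Pairs per resampling category (default 1000).
#' @param bins Quantile bins for mutation profiles (default 5).
#' @param min_detect Detection-fraction filter (default 0.5).
#' @param log_transform Log10 before standardization (default `TRUE`).
#' @param seed Integer master seed for the resampling stages.
#' @param outdir Optional directory; when given, per-stage TSVs and the JSON
#'   report are written there via [write_report()].
#' @return A `bowtie_report`: list with `features` (per-protein table joined
#'   with conservation and layers), `correlations`, `layer_summary`,
#'   `exclusive_multiple`, `ppi` (per-category |dlogF| distributions and
#'   comparisons), `mutations` (comparisons, profiles, enrichment), and
#'   `manifest` (parameters, seeds, universe counts, config hash).
#' @export
run_pipeline <- function(world, alpha = 0.01, n_pairs = 1000, bins = 5,
                         min_detect = 0.5, log_transform = TRUE, seed = 1L,
                         outdir = NULL) {
  stopifnot(all(c("intensities", "homology", "tree", "pathways", "edges",
                  "mutations") %in% names(world)))

  feats <- protein_features(world$intensities, min_detect = min_detect,
                            log_transform = log_transform)
  cons <- conservation_score(world$homology, world$tree,
                             reference = REFERENCE_SPECIES,
                             check_universe = FALSE)
  feats <- feats |>
    dplyr::left_join(dplyr::select(cons, "protein_id",
                                   conservation = "score"),
                     by = "protein_id")
  layers <- annotate_layers(world$pathways)

  correlations <- dplyr::bind_rows(
    conservation_vs_abundance = feature_correlation(feats$conservation,
                                                    feats$mean_abundance),
    conservation_vs_log_f = feature_correlation(feats$conservation,
                                                feats$log10_f),
    raw_sd_vs_abundance = feature_correlation(feats$raw_sd,
                                              feats$mean_abundance),
    log_f_vs_abundance = feature_correlation(feats$log10_f,
                                             feats$mean_abundance),
    .id = "pair"
  )

  layer_summary <- layer_feature_summary(feats, layers, alpha = alpha)
  excl <- split_exclusive_multiple(world$pathways, feats, alpha = alpha)

  ppi <- run_ppi_stage(world$edges, layers, feats, n_pairs = n_pairs,
                       alpha = alpha, seed = seed)
  mutations <- run_mutation_stage(feats, world$mutations, world$pathways,
                                  bins = bins, alpha = alpha)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bowtievar")),
    parameters = list(alpha = alpha, n_pairs = n_pairs, bins = bins,
                      min_detect = min_detect, log_transform = log_transform,
                      seed = seed),
    input_hash = rlang::hash(list(world$intensities, world$homology,
                                  ape::write.tree(world$tree), world$pathways,
                                  world$edges, world$mutations)),
    counts = list(
      proteins_in = nrow(world$intensities),
      proteins_detected = nrow(feats),
      proteins_with_finite_f = sum(is.finite(feats$log10_f)),
      layer_sizes = as.list(table(layers$layer)),
      edges = nrow(world$edges)
    )
  )

  report <- structure(
    list(features = feats, layers = layers, correlations = correlations,
         layer_summary = layer_summary, exclusive_multiple = excl,
         ppi = ppi, mutations = mutations, manifest = manifest),
    class = "bowtie_report"
  )
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

run_ppi_stage <- function(edges, layers, feats, n_pairs, alpha, seed) {
  elig <- eligible_proteins(layers, feats)
  sizes <- table(elig$layer)
  if (any(!c("input", "transmission") %in% names(sizes))) {
    warning("run_pipeline(): PPI stage skipped (missing populated layers)")
    return(NULL)
  }
  samp <- function(cat) {
    sample_pairs(edges, layers, feats, cat, n = n_pairs,
                 seed = stage_seed(seed, paste0("pairs-", cat)))
  }
  samples <- list(
    "PPI-IT" = samp("PPI-IT"),
    "PPI-TO" = samp("PPI-TO"),
    "PPI-W" = samp("PPI-W"),
    "PPI-Rand" = samp("PPI-Rand"),
    "Rand-IT" = samp("Rand-IT")
  )
  samples[["Perm-IT"]] <- permute_links(samples[["PPI-IT"]],
                                        seed = stage_seed(seed, "perm-it"))
  dists <- lapply(samples, abs_variability_diff)
  comparisons <- purrr::map_dfr(
    setdiff(names(samples), "PPI-IT"),
    function(cat) {
      tidy(compare_pair_distributions(samples[["PPI-IT"]], samples[[cat]],
                                      alpha = alpha))
    }
  )
  medians <- tibble::tibble(
    category = names(dists),
    n = lengths(dists),
    median_abs_diff = vapply(dists, stats::median, numeric(1))
  )
  list(samples = samples, distributions = dists, medians = medians,
       comparisons = comparisons)
}

run_mutation_stage <- function(feats, counts, pathways, bins, alpha) {
  present <- intersect(counts$protein_id, feats$protein_id)
  if (length(present) == 0L) {
    warning("run_pipeline(): mutation stage skipped (no overlapping proteins)")
    return(NULL)
  }
  feature_cols <- c("conservation", "log10_f", "mean_abundance")
  comparisons <- purrr::map_dfr(feature_cols, function(fc) {
    dplyr::mutate(tidy(mutation_class_comparison(feats, counts, fc,
                                                 alpha = alpha)),
                  feature = fc, .before = 1)
  })
  profiles <- lapply(
    stats::setNames(feature_cols, feature_cols),
    function(fc) binned_mutation_profile(feats, counts, fc, k = bins)
  )
  # enrichment of pathway terms among the conservation extremes,
  # with all annotated proteins as background
  ann <- pathways |>
    dplyr::filter(.data$protein_id %in% feats$protein_id) |>
    dplyr::distinct(.data$protein_id, .data$pathway_id)
  background <- unique(ann$protein_id)
  cons <- feats[feats$protein_id %in% background &
                  is.finite(feats$conservation), ]
  enrichment <- NULL
  if (nrow(cons) >= 2 * bins &&
      length(unique(cons$conservation)) >= bins) {
    cb <- quantile_bin(cons$conservation, bins)
    terms <- split(ann$protein_id, ann$pathway_id)
    enrichment <- list(
      low_conservation = enrichment_test(cons$protein_id[cb == 1L],
                                         terms, background),
      high_conservation = enrichment_test(cons$protein_id[cb == bins],
                                          terms, background)
    )
  }
  list(comparisons = comparisons, profiles = profiles,
       enrichment = enrichment)
}

#' @export
print.bowtie_report <- function(x, ...) {
  cat("bowtievar pipeline report\n")
  cat(sprintf("  %d proteins with features (%d finite F)\n",
              x$manifest$counts$proteins_detected,
              x$manifest$counts$proteins_with_finite_f))
  cat("\nFeature correlations:\n")
  print(x$correlations)
  cat("\nLayer comparisons:\n")
  print(x$layer_summary$comparisons, n = Inf)
  if (!is.null(x$ppi)) {
    cat("\nPPI |d log F| comparisons (vs PPI-IT):\n")
    print(x$ppi$comparisons, n = Inf)
  }
  if (!is.null(x$mutations)) {
    cat("\nSomatic vs germline comparisons:\n")
    print(x$mutations$comparisons, n = Inf)
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Writes the per-protein feature table, layer annotation, per-category
#' |d log F| distributions and binned mutation profiles as TSVs, and a
#' single `report.json` holding every comparison, correlation, profile and
#' the manifest. The JSON is deterministic for identical inputs and seeds; a
#' `generated` timestamp is the only run-dependent field.
#'
#' @param report A `bowtie_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "bowtie_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_tsv(report$features, p("features.tsv"), na = "")
  readr::write_tsv(report$layers, p("layers.tsv"), na = "")
  if (!is.null(report$ppi)) {
    dist_tbl <- purrr::imap_dfr(report$ppi$distributions, function(d, cat) {
      tibble::tibble(category = cat, abs_log_f_diff = d)
    })
    readr::write_tsv(dist_tbl, p("pair_distributions.tsv"), na = "")
  }
  if (!is.null(report$mutations)) {
    prof_tbl <- purrr::imap_dfr(report$mutations$profiles, function(pr, fc) {
      dplyr::mutate(tibble::as_tibble(pr), feature = fc, .before = 1)
    })
    readr::write_tsv(prof_tbl, p("mutation_profiles.tsv"), na = "")
  }
  json <- list(
    generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    manifest = report$manifest,
    correlations = report$correlations,
    layer_summary = report$layer_summary$summary,
    layer_comparisons = report$layer_summary$comparisons,
    exclusive_multiple = list(
      n_exclusive = length(report$exclusive_multiple$exclusive),
      n_multiple = length(report$exclusive_multiple$multiple),
      comparisons = report$exclusive_multiple$comparisons,
      class_fold = report$exclusive_multiple$class_fold
    ),
    ppi = if (!is.null(report$ppi)) {
      list(medians = report$ppi$medians, comparisons = report$ppi$comparisons)
    },
    mutations = if (!is.null(report$mutations)) {
      list(
        comparisons = report$mutations$comparisons,
        profiles = lapply(report$mutations$profiles, tibble::as_tibble),
        enrichment = report$mutations$enrichment
      )
    }
  )
  jsonlite::write_json(json, p("report.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(dir)
}
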