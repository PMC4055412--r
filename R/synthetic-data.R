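#' Per-protein ground truth of a synthetic world
#'
#' Draws the latent quantities every generated table is built from: latent
#' log10 abundance, bow-tie layer, the abundance-dependent noise scale, and
#' the planted between-cell and within-cell noise sds (layer multiplier
#' applied to the between component, independent lognormal jitter on both).
#' The variability stratum (above/below the layer's median between-to-within
#' sd ratio, the noise-free analogue of F) drives assortative wiring.
#'
#' @param config A [world_config()].
#' @return Tibble with `protein_id`, `latent_abundance`, `layer`,
#'   `noise_scale`, `sigma_between`, `sigma_within`, `high_variability`.
#' @export
world_truth <- function(config) {
  validate_world_config(config)
  withr::with_seed(stage_seed(config$seed, "truth"), {
    n <- config$n_proteins
    a <- stats::rnorm(n, config$abundance_log_mean, config$abundance_log_sd)
    layer <- sample(LAYER_NAMES, n, replace = TRUE,
                    prob = config$layer_fractions[LAYER_NAMES])
    z <- (a - config$abundance_log_mean) / config$abundance_log_sd
    scale <- 10^(-config$noise_abundance_exponent * (a - config$abundance_log_mean))
    mult <- config$layer_variability_multipliers[layer]
    sigma_b <- config$between_sd * sqrt(mult) * scale *
      exp(stats::rnorm(n, 0, config$sd_jitter))
    sigma_w <- config$within_sd * scale * exp(stats::rnorm(n, 0, config$sd_jitter))
    out <- tibble::tibble(
      protein_id = sprintf("P%05d", seq_len(n)),
      latent_abundance = a,
      layer = unname(layer),
      noise_scale = scale,
      sigma_between = unname(sigma_b),
      sigma_within = sigma_w
    )
    out |>
      dplyr::group_by(.data$layer) |>
      dplyr::mutate(high_variability =
                      .data$sigma_between / .data$sigma_within >
                      stats::median(.data$sigma_between / .data$sigma_within)) |>
      dplyr::ungroup()
  })
}

#' Generate a replicated multi-cell-line intensity matrix
#'
#' Log10-scale intensities are latent abundance + a per-(protein, cell line)
#' offset with the planted between-cell sd + replicate noise with the
#' planted within-cell sd; values are exponentiated on output since MS
#' intensities are approximately log-normal. Missingness is
#' missing-at-low-abundance: each protein's per-cell missingness probability
#' is logistic in latent abundance, with the threshold calibrated so the
#' expected overall missing fraction matches the configuration.
#'
#' @param config A [world_config()].
#' @param truth Optional precomputed [world_truth()] (regenerated from the
#'   config seed if omitted, so standalone calls match [generate_world()]).
#' @return Intensity tibble: `protein_id` plus one column per sample named
#'   `<cell_line>.<replicate>`, raw (exponentiated) intensities with `NA`
#'   for missing cells.
#' @export
generate_intensities <- function(config, truth = NULL) {
  validate_world_config(config)
  if (is.null(truth)) truth <- world_truth(config)
  lines <- cell_line_names(config$n_cell_lines)
  n <- config$n_proteins
  r <- config$n_replicates
  withr::with_seed(stage_seed(config$seed, "intensities"), {
    cols <- list()
    for (line in lines) {
      offset <- stats::rnorm(n, 0, truth$sigma_between)
      for (rep in seq_len(r)) {
        cols[[paste(line, rep, sep = ".")]] <-
          truth$latent_abundance + offset + stats::rnorm(n, 0, truth$sigma_within)
      }
    }
    v <- do.call(cbind, cols)
    if (config$missing_fraction > 0) {
      p_miss <- missingness_probability(truth$latent_abundance,
                                        config$missing_fraction,
                                        config$missing_steepness)
      drop <- matrix(stats::runif(length(v)) <
                       rep(p_miss, times = ncol(v)), nrow = n)
      v[drop] <- NA_real_
    }
    dplyr::bind_cols(tibble::tibble(protein_id = truth$protein_id),
                     tibble::as_tibble(10^v))
  })
}

cell_line_names <- function(n) {
  if (n <= length(PANEL_CELL_LINES)) return(PANEL_CELL_LINES[seq_len(n)])
  c(PANEL_CELL_LINES,
    sprintf("CL%02d", seq_len(n - length(PANEL_CELL_LINES))))
}

# logistic missing-at-low-abundance: threshold calibrated so that the mean
# missingness probability equals the target fraction
missingness_probability <- function(abundance, fraction, steepness) {
  f <- function(thr) mean(stats::plogis((thr - abundance) / steepness)) - fraction
  lo <- min(abundance) - 20 * steepness
  hi <- max(abundance) + 20 * steepness
  thr <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  stats::plogis((thr - abundance) / steepness)
}

#' Generate the weighted species tree
#'
#' A random binary topology over the configured species plus the reference,
#' with strictly positive branch lengths. The reference tip is always
#' present.
#'
#' @param config A [world_config()].
#' @return An [ape::phylo] tree.
#' @export
generate_species_tree <- function(config) {
  validate_world_config(config)
  withr::with_seed(stage_seed(config$seed, "tree"), {
    labels <- c(REFERENCE_SPECIES, config$species)
    tree <- ape::rtree(length(labels), tip.label = sample(labels),
                       br = function(k) stats::runif(k, 0.02, 0.3))
    validate_species_tree(tree)
    tree
  })
}

#' Generate the protein-to-species homology table
#'
#' Each non-reference species is retained in a protein's homology set with a
#' logistic probability that decreases with the species' tree distance from
#' the reference and increases with latent abundance (planting the
#' conservation-abundance association) and the protein's layer shift
#' (planting the bell-shaped layer conservation profile). The reference
#' species is always present.
#'
#' @inheritParams generate_intensities
#' @param tree The species tree (from [generate_species_tree()]).
#' @return Tibble with `protein_id` and comma-separated `species` (the
#'   reference included).
#' @export
generate_homology <- function(config, truth = NULL, tree = NULL) {
  validate_world_config(config)
  if (is.null(truth)) truth <- world_truth(config)
  if (is.null(tree)) tree <- generate_species_tree(config)
  withr::with_seed(stage_seed(config$seed, "homology"), {
    d <- ape::cophenetic.phylo(tree)[REFERENCE_SPECIES, config$species]
    d <- d / max(d)
    z <- (truth$latent_abundance - config$abundance_log_mean) /
      config$abundance_log_sd
    shift <- config$layer_conservation_shifts[truth$layer]
    sets <- character(config$n_proteins)
    logit_base <- config$retention_intercept +
      config$conservation_abundance_effect * z + shift
    for (i in seq_len(config$n_proteins)) {
      p <- stats::plogis(logit_base[i] - config$retention_distance_decay * d)
      kept <- config$species[stats::runif(length(d)) < p]
      sets[i] <- paste(c(REFERENCE_SPECIES, kept), collapse = ",")
    }
    tibble::tibble(protein_id = truth$protein_id, species = sets)
  })
}

#' Generate pathway membership and functional-class annotations
#'
#' Proteins receive one pathway plus a Poisson number of extras (boosted for
#' the transmission layer, planting the overrepresentation of transmission
#' classes among multi-pathway proteins). Functional classes follow the
#' layer: receptors in the input layer, transcription factors in the output
#' layer, kinases/phosphatases/adaptors/GTPase-binding (Reactome-style) or
#' mediators/cofactors (SignaLink-style) in the transmission layer, and
#' ligand or `none` outside. A small configured fraction of classed proteins
#' receives a second conflicting class to exercise the ambiguity rule.
#'
#' @inheritParams generate_intensities
#' @return Pathway tibble with `protein_id`, `pathway_id`, `source`,
#'   `raw_class` (one row per membership).
#' @export
generate_pathways <- function(config, truth = NULL) {
  validate_world_config(config)
  if (is.null(truth)) truth <- world_truth(config)
  withr::with_seed(stage_seed(config$seed, "pathways"), {
    n <- config$n_proteins
    labels <- if (config$n_pathways <= length(REACTOME_PATHWAY_LABELS)) {
      REACTOME_PATHWAY_LABELS[seq_len(config$n_pathways)]
    } else {
      c(REACTOME_PATHWAY_LABELS,
        sprintf("PW%02d", seq_len(config$n_pathways - length(REACTOME_PATHWAY_LABELS))))
    }
    rate <- config$pathway_multi_rate * config$pathway_multi_boost[truth$layer]
    n_pw <- pmin(1L + stats::rpois(n, rate), config$n_pathways)

    reactome_tm <- c("kinase", "phosphatase", "adaptor", "gtpase_binding")
    signalink_tm <- c("mediator", "cofactor")
    class_of <- character(n)
    source_of <- sample(c("reactome", "signalink"), n, replace = TRUE)
    is_in <- truth$layer == "input"
    is_out <- truth$layer == "output"
    is_tm <- truth$layer == "transmission"
    is_other <- truth$layer == "other"
    class_of[is_in] <- "receptor"
    class_of[is_out] <- "transcription_factor"
    tm_signalink <- is_tm & stats::runif(n) < 0.5
    tm_reactome <- is_tm & !tm_signalink
    class_of[tm_reactome] <- sample(reactome_tm, sum(tm_reactome), replace = TRUE)
    source_of[tm_reactome] <- "reactome"
    class_of[tm_signalink] <- sample(signalink_tm, sum(tm_signalink), replace = TRUE)
    source_of[tm_signalink] <- "signalink"
    class_of[is_other] <- sample(c("none", "ligand"), sum(is_other),
                                 replace = TRUE, prob = c(0.8, 0.2))

    first_pw <- sample(labels, n, replace = TRUE)
    rows <- tibble::tibble(
      protein_id = truth$protein_id,
      pathway_id = first_pw,
      source = source_of,
      raw_class = class_of
    )
    multi <- which(n_pw > 1L)
    if (length(multi) > 0L) {
      extra_rows <- purrr::map_dfr(multi, function(i) {
        tibble::tibble(
          protein_id = truth$protein_id[i],
          pathway_id = sample(setdiff(labels, first_pw[i]), n_pw[i] - 1L),
          source = source_of[i],
          raw_class = class_of[i]
        )
      })
      rows <- dplyr::bind_rows(rows, extra_rows)
    }

    # conflicting second class for a small fraction of classed proteins
    classed <- which(!class_of %in% c("none", "ligand"))
    n_amb <- round(config$ambiguous_fraction * length(classed))
    if (n_amb > 0) {
      amb <- sample(classed, n_amb)
      extra <- purrr::map_dfr(amb, function(i) {
        other <- sample(setdiff(setdiff(VALID_RAW_CLASSES, c("none", "ligand")),
                                class_of[i]), 1)
        tibble::tibble(
          protein_id = truth$protein_id[i],
          pathway_id = rows$pathway_id[match(truth$protein_id[i], rows$protein_id)],
          source = source_of[i],
          raw_class = other
        )
      })
      rows <- dplyr::bind_rows(rows, extra)
    }
    dplyr::arrange(rows, .data$protein_id, .data$pathway_id)
  })
}

#' Generate the PPI edge list
#'
#' Edges are drawn in four strata: input-transmission, transmission-output,
#' within-layer, and unrestricted pairs among layer-annotated proteins, in
#' the configured proportions. Input-transmission edges are
#' variability-assortative: with probability `wiring_assortativity` the input
#' endpoint comes from the high-variability half of the input layer and the
#' transmission endpoint from the low-variability half of the transmission
#' layer; otherwise both are uniform. Self-loops and duplicates are removed.
#'
#' @inheritParams generate_intensities
#' @return Edge tibble with `protein_a`, `protein_b` (canonical order).
#' @export
generate_edges <- function(config, truth = NULL) {
  validate_world_config(config)
  if (is.null(truth)) truth <- world_truth(config)
  withr::with_seed(stage_seed(config$seed, "edges"), {
    ids_of <- function(layer, strat = NULL) {
      keep <- truth$layer == layer
      if (!is.null(strat)) keep <- keep & truth$high_variability == strat
      truth$protein_id[keep]
    }
    inputs <- ids_of("input")
    transm <- ids_of("transmission")
    outputs <- ids_of("output")
    layered <- truth$protein_id[truth$layer != "other"]
    if (length(inputs) < 2 || length(transm) < 2 || length(outputs) < 2) {
      stop("generate_edges(): a bow-tie layer has fewer than 2 proteins")
    }
    n_cat <- round(config$n_edges * config$edge_category_mix[c("it", "to",
                                                               "within", "random")])
    # assortative edges: partner variabilities are anti-coupled in rank
    # (countermonotone over the two layers: the more variable the input
    # endpoint, the more stable its transmission partner). This makes the
    # within-pair |d log F| of true edges exceed both random input x
    # transmission pairings and rank-destroying permutations of the same
    # endpoints, which marginal (stratum-only) enrichment cannot do.
    ratio_of <- stats::setNames(truth$sigma_between / truth$sigma_within,
                                truth$protein_id)
    in_sorted <- inputs[order(ratio_of[inputs])]
    tm_sorted <- transm[order(ratio_of[transm])]
    draw_it <- function(m) {
      assort <- stats::runif(m) < config$wiring_assortativity
      a <- character(m)
      b <- character(m)
      k <- sum(assort)
      u <- stats::rbeta(k, 0.4, 0.4)
      jitterq <- function(q, k) pmin(pmax(q + stats::runif(k, -0.05, 0.05),
                                          1e-9), 1)
      a[assort] <- in_sorted[ceiling(jitterq(u, k) * length(in_sorted))]
      b[assort] <- tm_sorted[ceiling(jitterq(1 - u, k) * length(tm_sorted))]
      a[!assort] <- sample(inputs, sum(!assort), replace = TRUE)
      b[!assort] <- sample(transm, sum(!assort), replace = TRUE)
      tibble::tibble(a = a, b = b)
    }
    draw_to <- function(m) {
      tibble::tibble(a = sample(transm, m, replace = TRUE),
                     b = sample(outputs, m, replace = TRUE))
    }
    draw_within <- function(m) {
      pools <- list(inputs, transm, outputs)
      sizes <- vapply(pools, length, integer(1))
      which_layer <- sample(3, m, replace = TRUE, prob = sizes^2)
      a <- character(m)
      b <- character(m)
      for (l in 1:3) {
        k <- which_layer == l
        a[k] <- sample(pools[[l]], sum(k), replace = TRUE)
        b[k] <- sample(pools[[l]], sum(k), replace = TRUE)
      }
      tibble::tibble(a = a, b = b)
    }
    draw_random <- function(m) {
      tibble::tibble(a = sample(layered, m, replace = TRUE),
                     b = sample(layered, m, replace = TRUE))
    }
    draw_cat <- function(fn, target) {
      got <- tibble::tibble(protein_a = character(0), protein_b = character(0))
      tries <- 0L
      while (nrow(got) < target && tries < 50L) {
        cand <- fn(max(target - nrow(got) + 20L, 50L))
        cand <- cand[cand$a != cand$b, , drop = FALSE]
        got <- dplyr::distinct(dplyr::bind_rows(
          got, tibble::tibble(protein_a = pmin(cand$a, cand$b),
                              protein_b = pmax(cand$a, cand$b))))
        tries <- tries + 1L
      }
      got[seq_len(min(target, nrow(got))), , drop = FALSE]
    }
    dplyr::distinct(dplyr::bind_rows(
      draw_cat(draw_it, n_cat[["it"]]),
      draw_cat(draw_to, n_cat[["to"]]),
      draw_cat(draw_within, n_cat[["within"]]),
      draw_cat(draw_random, n_cat[["random"]])
    ))
  })
}

#' Generate per-protein mutation counts
#'
#' Proteins are binned into conservation quantile bins and each mutation
#' class's count is drawn Poisson with the configured per-bin rate, so the
#' binned-profile pipeline can recover the planted rates.
#'
#' @inheritParams generate_homology
#' @param scores Optional conservation-score tibble (from
#'   [conservation_score()]); recomputed from the generated homology and tree
#'   when omitted.
#' @return List with `counts` (tibble `protein_id`, `n_somatic`,
#'   `n_germline`, `n_snp`) and `rates` (tibble `class`, `bin`, `rate`).
#' @export
generate_mutations <- function(config, truth = NULL, tree = NULL,
                               scores = NULL) {
  validate_world_config(config)
  if (is.null(truth)) truth <- world_truth(config)
  if (is.null(scores)) {
    if (is.null(tree)) tree <- generate_species_tree(config)
    homology <- generate_homology(config, truth, tree)
    scores <- conservation_score(homology, tree, reference = REFERENCE_SPECIES,
                                 check_universe = FALSE)
  }
  stopifnot(identical(scores$protein_id, truth$protein_id))
  withr::with_seed(stage_seed(config$seed, "mutations"), {
    bins <- quantile_bin(scores$score, config$mutation_bins)
    draw <- function(class) {
      stats::rpois(config$n_proteins,
                   config$mutation_profile_shapes[[class]][bins])
    }
    counts <- tibble::tibble(
      protein_id = truth$protein_id,
      n_somatic = draw("somatic"),
      n_germline = draw("germline"),
      n_snp = draw("snp")
    )
    rates <- purrr::map_dfr(MUTATION_CLASSES, function(cl) {
      tibble::tibble(class = cl, bin = seq_len(config$mutation_bins),
                     rate = config$mutation_profile_shapes[[cl]])
    })
    list(counts = counts, rates = rates)
  })
}

#' Generate a complete synthetic world
#'
#' Draws all six input tables from one configuration with mutually
#' consistent protein identifiers and the planted effects described in
#' [world_config()]. The same config and seed always produce byte-identical
#' tables; each table comes from an independent seed stream, so standalone
#' generator calls (e.g. [generate_intensities()]) reproduce the
#' corresponding component exactly.
#'
#' @param config A [world_config()].
#' @return A `bowtie_world` list: `intensities`, `homology`, `tree`,
#'   `pathways`, `edges`, `mutations`, and `truth` (config, per-protein
#'   latent table, conservation scores, planted mutation rates).
#' @export
generate_world <- function(config = world_config()) {
  validate_world_config(config)
  truth <- world_truth(config)
  tree <- generate_species_tree(config)
  homology <- generate_homology(config, truth, tree)
  scores <- conservation_score(homology, tree, reference = REFERENCE_SPECIES,
                               check_universe = FALSE)
  mut <- generate_mutations(config, truth, tree, scores)
  structure(
    list(
      intensities = generate_intensities(config, truth),
      homology = homology,
      tree = tree,
      pathways = generate_pathways(config, truth),
      edges = generate_edges(config, truth),
      mutations = mut$counts,
      truth = list(config = config, proteins = truth,
                   conservation = scores, mutation_rates = mut$rates)
    ),
    class = "bowtie_world"
  )
}

#' @export
print.bowtie_world <- function(x, ...) {
  cfg <- x$truth$config
  cat("Synthetic bow-tie world\n")
  cat(sprintf("  %d proteins, %d cell lines x %d replicates, %d species tips\n",
              cfg$n_proteins, cfg$n_cell_lines, cfg$n_replicates,
              length(x$tree$tip.label)))
  cat(sprintf("  %d pathway rows, %d PPI edges, seed %d\n",
              nrow(x$pathways), nrow(x$edges), cfg$seed))
  invisible(x)
}
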