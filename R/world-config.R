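PANEL_CELL_LINES <- c("A549", "GAMG", "HEK293", "Hela", "HepG2", "Jurkat",
                       "K562", "LnCap", "MCF7", "RKO", "U2OS")

HOMOLOGY_SPECIES <- c(
  "Pan_troglodytes", "Mus_musculus", "Rattus_norvegicus", "Gallus_gallus",
  "Danio_rerio", "Drosophila_melanogaster", "Anopheles_gambiae",
  "Caenorhabditis_elegans", "Schizosaccharomyces_pombe",
  "Saccharomyces_cerevisiae", "Eremothecium_gossypii",
  "Arabidopsis_thaliana", "Oryza_sativa"
)

REFERENCE_SPECIES <- "Homo_sapiens"

REACTOME_PATHWAY_LABELS <- c("DR", "MO", "GE", "MT", "MB", "ST", "AP", "DB",
                             "TM", "CO")

LAYER_NAMES <- c("input", "transmission", "output", "other")

#' Synthetic-world configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' the package's reference study conditions: an 11-cell-line, 3-replicate
#' proteomics design; log-normal protein abundances whose measurement spread
#' shrinks with abundance (the classic MS abundance-variability confound);
#' a bow-tie layer structure in which the input layer carries four times the
#' between-cell variance of the transmission and output layers; species
#' retention (hence conservation) that rises with abundance and peaks in the
#' transmission layer; variability-assortative wiring between the input and
#' transmission layers; and Poisson mutation counts with bell-shaped
#' somatic/germline per-bin rates over conservation quintiles against a
#' flatter SNP background.
#'
#' @param n_proteins Number of proteins.
#' @param n_cell_lines Number of cell lines (default 11; the first 11 use the
#'   canonical cancer cell-line names).
#' @param n_replicates Replicates per cell line (default 3).
#' @param abundance_log_mean,abundance_log_sd Mean and sd of latent log10
#'   abundance.
#' @param between_sd,within_sd Baseline between-cell-line and replicate noise
#'   sd (log10 units) at mean abundance, before layer multipliers and jitter.
#' @param noise_abundance_exponent Slope `a` of the confound: per-protein
#'   noise scales as `abundance^(-a)` (0 disables it).
#' @param sd_jitter Lognormal sd (natural log) of independent per-protein
#'   jitter on both noise components.
#' @param missing_fraction Overall expected fraction of missing cells,
#'   concentrated in low-abundance proteins via a logistic mechanism.
#' @param missing_steepness Logistic scale (log10 abundance units) of the
#'   missingness mechanism.
#' @param layer_fractions Named proportions over
#'   `input/transmission/output/other`; must sum to 1.
#' @param layer_variability_multipliers Named per-layer multipliers (> 0) on
#'   the between-cell variance.
#' @param conservation_abundance_effect Logit-scale slope of species
#'   retention on standardized latent abundance.
#' @param layer_conservation_shifts Named logit-scale per-layer shifts of
#'   species retention (bell-shaped defaults: transmission high).
#' @param retention_intercept,retention_distance_decay Logit intercept and
#'   distance decay of species retention; distances are tree distances from
#'   the reference species scaled to `[0, 1]`.
#' @param wiring_assortativity Probability in `[0, 1]` that an
#'   input-transmission edge draws its input endpoint from the
#'   top-variability half of the input layer and its transmission endpoint
#'   from the bottom-variability half of the transmission layer.
#' @param n_pathways Number of pathways (default 10, canonical labels).
#' @param pathway_multi_rate Poisson rate of extra pathway memberships;
#'   multiplied by `pathway_multi_boost` for the protein's layer.
#' @param pathway_multi_boost Named per-layer multiplier on
#'   `pathway_multi_rate` (default boosts transmission 3x).
#' @param ambiguous_fraction Fraction of classed proteins given a second,
#'   conflicting functional-class annotation.
#' @param n_edges Total PPI edges generated.
#' @param edge_category_mix Named proportions of edges over
#'   `it/to/within/random`; must sum to 1.
#' @param mutation_bins Number of conservation bins used when planting
#'   mutation rates.
#' @param mutation_profile_shapes Named list (`somatic`, `germline`, `snp`)
#'   of per-bin Poisson rates, each of length `mutation_bins`.
#' @param species Non-reference species names (tips of the generated tree,
#'   together with the reference).
#' @param seed Integer master seed; fully determines all outputs.
#' @return A validated `world_config` list.
#' @export
world_config <- function(n_proteins = 2000,
                         n_cell_lines = 11,
                         n_replicates = 3,
                         abundance_log_mean = 7,
                         abundance_log_sd = 1,
                         between_sd = 0.25,
                         within_sd = 0.25,
                         noise_abundance_exponent = 0.2,
                         sd_jitter = 0.8,
                         missing_fraction = 0.05,
                         missing_steepness = 0.25,
                         layer_fractions = c(input = 0.15, transmission = 0.25,
                                             output = 0.10, other = 0.50),
                         layer_variability_multipliers = c(input = 4,
                                                           transmission = 1,
                                                           output = 1,
                                                           other = 1),
                         conservation_abundance_effect = 0.8,
                         layer_conservation_shifts = c(input = -1,
                                                       transmission = 1.5,
                                                       output = -1,
                                                       other = 0),
                         retention_intercept = 1,
                         retention_distance_decay = 4,
                         wiring_assortativity = 0.8,
                         n_pathways = 10,
                         pathway_multi_rate = 0.12,
                         pathway_multi_boost = c(input = 1, transmission = 3,
                                                 output = 1, other = 1),
                         ambiguous_fraction = 0.02,
                         n_edges = 5000,
                         edge_category_mix = c(it = 0.3, to = 0.2,
                                               within = 0.2, random = 0.3),
                         mutation_bins = 5,
                         mutation_profile_shapes = list(
                           somatic = c(0.5, 1, 2, 3, 1.5),
                           germline = c(1, 2, 3, 1.5, 0.5),
                           snp = c(3, 2.5, 2, 2, 1.5)
                         ),
                         species = HOMOLOGY_SPECIES,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "world_config"
  validate_world_config(cfg)
}

validate_world_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("world_config: ", msg, call. = FALSE)
  counts <- c("n_proteins", "n_cell_lines", "n_replicates", "n_pathways",
              "n_edges", "mutation_bins")
  for (nm in counts) {
    chk(is.numeric(cfg[[nm]]) && length(cfg[[nm]]) == 1 && cfg[[nm]] >= 1 &&
          cfg[[nm]] == round(cfg[[nm]]), paste(nm, "must be a count >= 1"))
  }
  chk(cfg$mutation_bins >= 2, "mutation_bins must be >= 2")
  chk(setequal(names(cfg$layer_fractions), LAYER_NAMES),
      "layer_fractions must be named over input/transmission/output/other")
  chk(abs(sum(cfg$layer_fractions) - 1) < 1e-9, "layer_fractions must sum to 1")
  chk(all(cfg$layer_fractions >= 0), "layer_fractions must be non-negative")
  for (nm in c("layer_variability_multipliers", "pathway_multi_boost")) {
    chk(setequal(names(cfg[[nm]]), LAYER_NAMES) && all(cfg[[nm]] > 0),
        paste(nm, "must be positive and named over the four layers"))
  }
  chk(setequal(names(cfg$layer_conservation_shifts), LAYER_NAMES),
      "layer_conservation_shifts must be named over the four layers")
  chk(cfg$wiring_assortativity >= 0 && cfg$wiring_assortativity <= 1,
      "wiring_assortativity must lie in [0, 1]")
  chk(cfg$missing_fraction >= 0 && cfg$missing_fraction < 1,
      "missing_fraction must lie in [0, 1)")
  chk(setequal(names(cfg$edge_category_mix), c("it", "to", "within", "random")) &&
        abs(sum(cfg$edge_category_mix) - 1) < 1e-9,
      "edge_category_mix must be named over it/to/within/random and sum to 1")
  chk(setequal(names(cfg$mutation_profile_shapes), MUTATION_CLASSES),
      "mutation_profile_shapes must name somatic/germline/snp")
  for (nm in MUTATION_CLASSES) {
    chk(length(cfg$mutation_profile_shapes[[nm]]) == cfg$mutation_bins &&
          all(cfg$mutation_profile_shapes[[nm]] >= 0),
        "each mutation profile shape must be a non-negative vector of length mutation_bins")
  }
  chk(all(c(cfg$between_sd, cfg$within_sd, cfg$abundance_log_sd) > 0),
      "sd parameters must be positive")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1 && cfg$seed == round(cfg$seed),
      "seed must be an integer")
  cfg
}

# Independent per-stage seed streams: a stable small hash of the stage name
# folded into the master seed, so toggling one stage never perturbs another.
stage_seed <- function(seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 9999991
  as.integer((abs(as.numeric(seed)) * 37 + h) %% 2147483629)
}
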