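#' Intensity-matrix helpers
#'
#' Intensity matrices travel as wide tibbles: a `protein_id` column followed
#' by one numeric column per MS run, named `<cell_line>.<replicate>`
#' (e.g. `A549.2`). `sample_cell_lines()` recovers the cell-line factor from
#' the column names by stripping the final `.replicate` suffix.
#'
#' @param matrix An intensity tibble as above.
#' @return Character vector of cell-line labels, one per sample column.
#' @export
sample_cell_lines <- function(matrix) {
  cols <- setdiff(names(matrix), "protein_id")
  sub("\\.[^.]*$", "", cols)
}

intensity_values <- function(matrix) {
  stopifnot(is.data.frame(matrix), "protein_id" %in% names(matrix))
  v <- as.matrix(matrix[setdiff(names(matrix), "protein_id")])
  storage.mode(v) <- "double"
  rownames(v) <- matrix$protein_id
  v
}

values_to_tibble <- function(values) {
  dplyr::bind_cols(tibble::tibble(protein_id = rownames(values)),
                   tibble::as_tibble(values))
}

#' Keep proteins detected in a minimum fraction of samples
#'
#' A protein counts as detected in a sample when its intensity is non-missing.
#' Proteins whose detected fraction falls below `min_fraction` are dropped;
#' the 50% default reproduces the usual "detected in at least half of the MS
#' replicates" rule, with the boundary kept (`>=`).
#'
#' @param matrix Intensity tibble (see [sample_cell_lines()]).
#' @param min_fraction Minimum detected fraction in (0, 1].
#' @return The filtered intensity tibble (columns unchanged).
#' @export
filter_detected <- function(matrix, min_fraction = 0.5) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  v <- intensity_values(matrix)
  frac <- rowMeans(!is.na(v))
  keep <- frac >= min_fraction
  if (!any(keep)) warning("filter_detected(): no protein passes the detection filter")
  matrix[keep, , drop = FALSE]
}

#' Standardize each sample column to mean 0, sd 1
#'
#' Each sample (MS run column) is centered and scaled over its detected
#' entries only: the column mean is subtracted and the column standard
#' deviation divides. Missing entries stay missing. By default intensities
#' are log10-transformed first, since MS intensities span several decades.
#'
#' @param matrix Intensity tibble.
#' @param log_transform Apply `log10` before standardizing (default `TRUE`).
#'   Requires strictly positive intensities.
#' @return Standardized intensity tibble.
#' @export
standardize_samples <- function(matrix, log_transform = TRUE) {
  v <- intensity_values(matrix)
  if (log_transform) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("standardize_samples(): non-positive intensities cannot be log-transformed")
    }
    v <- log10(v)
  }
  n_det <- colSums(!is.na(v))
  if (any(n_det < 2)) {
    stop("standardize_samples(): sample(s) with fewer than 2 detected proteins: ",
         paste(colnames(v)[n_det < 2], collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  sigma <- apply(v, 2, stats::sd, na.rm = TRUE)
  if (any(sigma == 0)) {
    stop("standardize_samples(): zero spread in sample(s): ",
         paste(colnames(v)[sigma == 0], collapse = ", "))
  }
  v <- sweep(sweep(v, 2, mu, "-"), 2, sigma, "/")
  values_to_tibble(v)
}

#' Per-protein mean of standardized intensities
#'
#' Row-wise arithmetic mean over non-missing entries. Proteins with no
#' detected value are dropped with a warning.
#'
#' @param std_matrix A standardized intensity tibble.
#' @return Tibble with `protein_id`, `mean_abundance`.
#' @export
mean_abundance <- function(std_matrix) {
  v <- intensity_values(std_matrix)
  n_det <- rowSums(!is.na(v))
  if (any(n_det == 0)) {
    warning("mean_abundance(): dropping ", sum(n_det == 0),
            " protein(s) with no detected value")
  }
  keep <- n_det > 0
  tibble::tibble(protein_id = rownames(v)[keep],
                 mean_abundance = unname(rowMeans(v[keep, , drop = FALSE],
                                                  na.rm = TRUE)))
}

#' Per-protein F value: between-cell over within-cell variability
#'
#' The variability statistic is the classical one-way ANOVA F on each
#' protein's detected standardized intensities, with the cell line as the
#' grouping factor and the actual (unbalanced) per-line detection counts:
#' \deqn{F = \frac{SS_B/(k-1)}{SS_W/(N-k)}}
#' where \eqn{k} is the number of cell lines with at least one detected
#' replicate and \eqn{N} the total detected count. Normalizing the
#' between-cell spread by the within-cell (replicate) spread removes the
#' dependence of raw variability on abundance. Proteins failing the
#' preconditions are returned with `f_value = NA` and a reason in `f_flag`;
#' zero within-cell spread yields an infinite F flagged `undefined_within`.
#'
#' @param std_matrix Standardized intensity tibble.
#' @param cell_lines Cell-line label per sample column; defaults to
#'   [sample_cell_lines()] of the column names.
#' @param min_lines Minimum number of cell lines with >= 1 detected replicate.
#' @param min_lines_with_reps Minimum number of cell lines with >= 2 detected
#'   replicates (so the within-cell mean square has df > 0).
#' @return Tibble with `protein_id`, `f_value`, `log10_f`, `df_between`,
#'   `df_within`, `f_flag` (`"ok"`, `"too_few_lines"`,
#'   `"too_few_replicated_lines"`, `"undefined_within"`).
#' @export
f_value <- function(std_matrix, cell_lines = NULL,
                    min_lines = 2, min_lines_with_reps = 2) {
  v <- intensity_values(std_matrix)
  if (is.null(cell_lines)) cell_lines <- sample_cell_lines(std_matrix)
  stopifnot(length(cell_lines) == ncol(v))
  lines <- unique(cell_lines)
  if (length(lines) < 2) stop("f_value(): need at least 2 cell lines")

  det <- !is.na(v)
  n_prot <- nrow(v)
  ssb_num <- numeric(n_prot)   # sum_g n_g * m_g^2 accumulated, centered later
  ssw <- numeric(n_prot)
  sum_all <- rowSums(v, na.rm = TRUE)
  n_all <- rowSums(det)
  k_lines <- numeric(n_prot)
  k_rep_lines <- numeric(n_prot)

  for (line in lines) {
    cols <- which(cell_lines == line)
    vg <- v[, cols, drop = FALSE]
    ng <- rowSums(det[, cols, drop = FALSE])
    sg <- rowSums(vg, na.rm = TRUE)
    mg <- ifelse(ng > 0, sg / ng, 0)
    ssb_num <- ssb_num + ng * mg^2
    resid <- vg - mg
    ssw <- ssw + rowSums(resid^2, na.rm = TRUE)
    k_lines <- k_lines + (ng > 0)
    k_rep_lines <- k_rep_lines + (ng > 1)
  }
  grand <- ifelse(n_all > 0, sum_all / n_all, NA_real_)
  ssb <- pmax(ssb_num - n_all * grand^2, 0)
  df_between <- k_lines - 1
  df_within <- n_all - k_lines

  flag <- rep("ok", n_prot)
  flag[k_lines < min_lines] <- "too_few_lines"
  flag[flag == "ok" & k_rep_lines < min_lines_with_reps] <- "too_few_replicated_lines"

  msb <- ssb / df_between
  msw <- ssw / df_within
  f <- msb / msw
  f[flag != "ok"] <- NA_real_
  zero_within <- flag == "ok" & msw == 0
  f[zero_within] <- Inf
  flag[zero_within] <- "undefined_within"

  n_dropped <- sum(!flag %in% c("ok", "undefined_within"))
  if (n_dropped > 0) {
    message("f_value(): ", n_dropped, " protein(s) excluded (insufficient detected replication)")
  }
  tibble::tibble(protein_id = rownames(v), f_value = unname(f),
                 log10_f = unname(log10(f)), df_between = unname(df_between),
                 df_within = unname(df_within), f_flag = flag)
}

#' Full per-protein feature table from a raw intensity matrix
#'
#' Chains the detection filter, per-sample standardization, mean abundance
#' and F value, and keeps the pre-standardization per-protein spread
#' (`raw_sd`, on the log scale when `log_transform` is on) for the
#' abundance-variability confound diagnostic.
#'
#' @inheritParams standardize_samples
#' @inheritParams f_value
#' @param min_detect Detection-fraction threshold (default 0.5).
#' @return Tibble with `protein_id`, `mean_abundance`, `f_value`, `log10_f`,
#'   `detected_fraction`, `raw_sd`, `f_flag`.
#' @export
protein_features <- function(matrix, min_detect = 0.5, log_transform = TRUE,
                             min_lines = 2, min_lines_with_reps = 2) {
  kept <- filter_detected(matrix, min_detect)
  v_raw <- intensity_values(kept)
  if (log_transform) v_raw <- log10(v_raw)
  raw <- tibble::tibble(
    protein_id = rownames(v_raw),
    detected_fraction = rowMeans(!is.na(v_raw)),
    raw_sd = apply(v_raw, 1, stats::sd, na.rm = TRUE)
  )
  std <- standardize_samples(kept, log_transform = log_transform)
  out <- mean_abundance(std) |>
    dplyr::inner_join(
      f_value(std, min_lines = min_lines,
              min_lines_with_reps = min_lines_with_reps) |>
        dplyr::select("protein_id", "f_value", "log10_f", "f_flag"),
      by = "protein_id"
    ) |>
    dplyr::inner_join(raw, by = "protein_id")
  dplyr::select(out, "protein_id", "mean_abundance", "f_value", "log10_f",
                "detected_fraction", "raw_sd", "f_flag")
}

#' Abundance-variability confound diagnostic
#'
#' Reports (a) the correlation between per-protein raw spread and mean
#' abundance — strongly negative in MS data, since abundant proteins are
#' measured more precisely — and (b) the correlation between log F and mean
#' abundance, which should be near zero once within-cell variance has
#' normalized the spread.
#'
#' @param features Output of [protein_features()] (needs `mean_abundance`,
#'   `log10_f`, `raw_sd`); at least 50 proteins.
#' @param method Correlation method, `"spearman"` (default) or `"pearson"`.
#' @return Tibble with one row per diagnostic (`quantity`,
#'   `estimate`, `p_value`, `n`, `undefined`).
#' @export
confound_check <- function(features, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  stopifnot(nrow(features) >= 50)
  ok <- is.finite(features$log10_f)
  dplyr::bind_rows(
    raw_sd_vs_mean = feature_correlation(features$raw_sd,
                                         features$mean_abundance, method),
    log_f_vs_mean = feature_correlation(features$log10_f[ok],
                                        features$mean_abundance[ok], method),
    .id = "quantity"
  )
}

#' Compare F values between two externally defined protein sets
#'
#' Runs the shared two-sided rank-sum test on log F between two reference
#' sets, e.g. housekeeping genes vs all other proteins, or mouse
#' low-variability vs high-variability orthologs.
#'
#' @param features Feature table with `protein_id` and `log10_f`.
#' @param set_a,set_b Character vectors of protein ids; each must intersect
#'   the feature table.
#' @param alpha Direction-calling threshold (default 0.01).
#' @param label_a,label_b Labels echoed into the result.
#' @return A [rank_sum_test()] `bowtie_comparison`.
#' @export
compare_reference_sets <- function(features, set_a, set_b, alpha = 0.01,
                                   label_a = "set_a", label_b = "set_b") {
  ok <- is.finite(features$log10_f)
  fa <- features$log10_f[ok & features$protein_id %in% set_a]
  fb <- features$log10_f[ok & features$protein_id %in% set_b]
  if (length(fa) == 0L || length(fb) == 0L) {
    stop("compare_reference_sets(): a set has empty intersection with the feature table")
  }
  rank_sum_test(fa, fb, alpha = alpha, label_a = label_a, label_b = label_b)
}

#' Low- and high-variability ortholog sets from a tissue intensity matrix
#'
#' For an unreplicated multi-tissue matrix (one column per tissue) the
#' within-sample variance cannot be estimated, so variability cannot be
#' normalized for abundance. Instead, only proteins detected in all tissues
#' and with above-average mean abundance are considered, and the lowest and
#' highest standard-deviation quartiles are extracted and mapped to reference
#' proteins through an ortholog table.
#'
#' @param mouse_matrix Intensity tibble, one column per tissue, no replicates.
#' @param ortholog_map Data frame with columns `source_id`, `target_id`
#'   mapping the matrix's protein ids to reference (human) ids; unmapped
#'   proteins are dropped.
#' @param log_transform Log10 before computing means/sds (default `TRUE`).
#' @return List with character vectors `low` and `high` of target ids.
#' @export
mouse_quartile_sets <- function(mouse_matrix, ortholog_map, log_transform = TRUE) {
  stopifnot(all(c("source_id", "target_id") %in% names(ortholog_map)))
  v <- intensity_values(mouse_matrix)
  if (log_transform) v <- log10(v)
  complete <- rowSums(is.na(v)) == 0
  v <- v[complete, , drop = FALSE]
  means <- rowMeans(v)
  v <- v[means > mean(means), , drop = FALSE]
  if (nrow(v) < 4) stop("mouse_quartile_sets(): fewer than 4 proteins pass the filters")
  sds <- apply(v, 1, stats::sd)
  q <- stats::quantile(sds, c(0.25, 0.75))
  low <- rownames(v)[sds <= q[[1]]]
  high <- rownames(v)[sds >= q[[2]]]
  map <- function(ids) {
    unique(ortholog_map$target_id[ortholog_map$source_id %in% ids])
  }
  out <- list(low = map(low), high = map(high))
  if (length(out$low) == 0L || length(out$high) == 0L) {
    stop("mouse_quartile_sets(): empty quartile set after ortholog mapping")
  }
  out
}
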