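#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-layer feature distributions
#'
#' Boxplots of each feature by bow-tie layer, the visual counterpart of the
#' pairwise layer comparisons.
#'
#' @param object A `bowtie_layer_summary` from [layer_feature_summary()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bowtie_layer_summary <- function(object, ...) {
  dat <- object$data |>
    dplyr::mutate(layer = factor(.data$layer,
                                 c("input", "transmission", "output")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$layer, y = .data$value,
                                    fill = .data$layer)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = "bow-tie layer", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a binned mutation profile
#'
#' Per-bin mean mutation counts for the somatic, germline and SNP classes
#' along the binned feature.
#'
#' @param object A `binned_profile` from [binned_mutation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.binned_profile <- function(object, ...) {
  ylab <- if (isTRUE(attr(object, "normalize"))) {
    "mean mutations per protein (class-normalized)"
  } else {
    "mean mutations per protein"
  }
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$bin, y = .data$mean_count,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0(attr(object, "feature"), " quantile bin"),
                  y = ylab, colour = "mutation class") +
    ggplot2::theme_minimal()
}

#' Plot |d log F| distributions of sampled pair categories
#'
#' Density curves of the absolute log-F differences per sampling category
#' from the pipeline's PPI stage.
#'
#' @param ppi The `ppi` element of a `bowtie_report`.
#' @return A ggplot object.
#' @export
plot_pair_distributions <- function(ppi) {
  stopifnot(is.list(ppi), "distributions" %in% names(ppi))
  dat <- purrr::imap_dfr(ppi$distributions, function(d, cat) {
    tibble::tibble(category = cat, abs_diff = d)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$abs_diff,
                                    colour = .data$category)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "|log10 F difference| within pair",
                  y = "density", colour = "pair category") +
    ggplot2::theme_minimal()
}
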