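#' Two-sided Wilcoxon-Mann-Whitney rank-sum test with fixed conventions
#'
#' All group comparisons in the package run through this wrapper so that every
#' report uses one convention: two-sided, mid-ranks for ties, exact null
#' distribution for small untied samples and the normal approximation with
#' continuity (and tie) correction otherwise. P-values are never clipped to
#' zero; underflow is reported at the smallest representable double and
#' flagged.
#'
#' @param a,b Numeric vectors, both non-empty. Missing values are dropped.
#' @param alpha Significance threshold used to call a direction
#'   (default 0.01). `direction` is `"none"` whenever `p_value >= alpha`.
#' @param exact_max_n Largest `min(length(a), length(b))` for which the exact
#'   null distribution is used (only when the pooled sample has no ties).
#' @param label_a,label_b Optional names for the two groups, echoed in output.
#'
#' @return An object of class `bowtie_comparison`: a list with elements
#'   `statistic` (the Mann-Whitney U for `a`), `p_value`, `direction`
#'   (`"higher"`/`"lower"`/`"none"`, the position of `a` relative to `b`),
#'   `n_a`, `n_b`, `alpha`, `exact`, `underflow`, `label_a`, `label_b`.
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), alpha = 0.05)
#' @export
rank_sum_test <- function(a, b, alpha = 0.01, exact_max_n = 10,
                          label_a = "a", label_b = "b") {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop("rank_sum_test(): both groups must be non-empty after removing non-finite values")
  }
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)

  if (length(unique(pooled)) == 1L) {
    # degenerate all-tied input: no evidence either way
    res <- list(statistic = n_a * n_b / 2, p_value = 1, exact = FALSE)
  } else {
    has_ties <- anyDuplicated(pooled) > 0L
    use_exact <- !has_ties && min(n_a, n_b) <= exact_max_n
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided",
                         exact = use_exact, correct = TRUE)
    )
    res <- list(statistic = unname(wt$statistic), p_value = wt$p.value,
                exact = use_exact)
  }

  underflow <- FALSE
  if (res$p_value <= 0) {
    res$p_value <- .Machine$double.xmin
    underflow <- TRUE
  }
  direction <- if (res$p_value >= alpha) {
    "none"
  } else if (res$statistic > n_a * n_b / 2) {
    "higher"
  } else {
    "lower"
  }

  structure(
    list(statistic = res$statistic, p_value = res$p_value,
         direction = direction, n_a = n_a, n_b = n_b, alpha = alpha,
         exact = res$exact, underflow = underflow,
         label_a = label_a, label_b = label_b),
    class = "bowtie_comparison"
  )
}

#' @export
print.bowtie_comparison <- function(x, ...) {
  cat("Wilcoxon-Mann-Whitney rank-sum test (two-sided)\n")
  cat(sprintf("  %s (n=%d) vs %s (n=%d)\n", x$label_a, x$n_a, x$label_b, x$n_b))
  cat(sprintf("  U = %.4g, p = %.4g%s (%s)\n", x$statistic, x$p_value,
              if (x$underflow) " [underflow]" else "",
              if (x$exact) "exact" else "normal approximation"))
  cat(sprintf("  direction of %s at alpha %.3g: %s\n",
              x$label_a, x$alpha, x$direction))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bowtie_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$label_a, group_b = x$label_b,
    statistic = x$statistic, p_value = x$p_value, direction = x$direction,
    n_a = x$n_a, n_b = x$n_b, significant_at = x$alpha
  )
}

#' @export
glance.bowtie_comparison <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, p_value = x$p_value, direction = x$direction,
    exact = x$exact, underflow = x$underflow
  )
}

#' Correlation between two paired features
#'
#' Spearman by default (rank-based, robust to the heavy-tailed intensity
#' scale), Pearson on request. Pairs with a missing value in either vector are
#' dropped; a zero-variance vector yields an undefined (flagged) estimate
#' rather than an error, so diagnostic sweeps can proceed.
#'
#' @param x,y Paired numeric vectors.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_pairs Minimum number of complete pairs required (default 10).
#' @return A one-row tibble with `method`, `estimate`, `p_value`, `n`, and a
#'   logical `undefined` flag.
#' @export
feature_correlation <- function(x, y, method = c("spearman", "pearson"),
                                min_pairs = 10) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < min_pairs) {
    stop("feature_correlation(): fewer than ", min_pairs, " complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(method = method, estimate = NA_real_,
                          p_value = NA_real_, n = n, undefined = TRUE))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  tibble::tibble(method = method, estimate = unname(ct$estimate),
                 p_value = ct$p.value, n = n, undefined = FALSE)
}
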