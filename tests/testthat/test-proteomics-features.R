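test_that("detection filter keeps the 50% boundary and matches a recount", {
  v <- matrix(1, nrow = 3, ncol = 6)
  v[1, 4:6] <- NA            # 3 of 6 detected: kept at equality
  v[2, 2:6] <- NA            # 1 of 6: dropped
  mat <- intensity_tibble(v, lines = rep(c("A", "B"), each = 3))
  kept <- filter_detected(mat, 0.5)
  expect_equal(kept$protein_id, c("P001", "P003"))

  withr::with_seed(8, {
    v2 <- matrix(runif(50 * 8), 50)
    v2[runif(length(v2)) < 0.4] <- NA
  })
  mat2 <- intensity_tibble(v2, lines = rep(c("A", "B", "C", "D"), each = 2))
  kept2 <- filter_detected(mat2, 0.5)
  brute <- mat2$protein_id[rowSums(!is.na(v2)) / ncol(v2) >= 0.5]
  expect_equal(kept2$protein_id, brute)
  # idempotence
  expect_identical(filter_detected(kept2, 0.5), kept2)
  # min_fraction 1 on a complete matrix is the identity
  full <- intensity_tibble(matrix(1:12, 3), lines = rep(c("A", "B"), each = 2))
  expect_identical(filter_detected(full, 1), full)
})

test_that("standardization gives per-sample mean 0 / sd 1 and is idempotent", {
  mat <- intensity_tibble(matrix(c(1, 2, 3, 10, 20, 40), ncol = 2),
                          lines = c("A", "B"), reps = c(1, 1))
  std <- standardize_samples(mat, log_transform = FALSE)
  expect_equal(std$A.1, c(-1, 0, 1))

  withr::with_seed(21, {
    v <- matrix(10^rnorm(200 * 6, 6), 200)
    v[sample(length(v), 100)] <- NA
  })
  m <- intensity_tibble(v, lines = rep(c("A", "B", "C"), each = 2))
  std2 <- standardize_samples(m)
  vals <- as.matrix(std2[-1])
  expect_equal(unname(colMeans(vals, na.rm = TRUE)), rep(0, 6),
               tolerance = 1e-9)
  expect_equal(unname(apply(vals, 2, sd, na.rm = TRUE)), rep(1, 6),
               tolerance = 1e-9)
  # missing entries stay missing
  expect_equal(is.na(vals), is.na(v), ignore_attr = TRUE)
  # idempotence (no further log)
  std3 <- standardize_samples(std2, log_transform = FALSE)
  expect_equal(as.matrix(std3[-1]), vals, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("zero-spread sample errors with the sample named", {
  mat <- intensity_tibble(matrix(c(1, 1, 1, 1, 2, 3), ncol = 2),
                          lines = c("A", "B"), reps = c(1, 1))
  expect_error(standardize_samples(mat, log_transform = FALSE),
               "zero spread.*A\\.1")
})

test_that("mean abundance is the row mean over detected entries", {
  mat <- intensity_tibble(matrix(c(-1, 5, 0, NA, 1, NA), nrow = 2),
                          lines = c("A", "B", "C"), reps = c(1, 1, 1))
  ma <- mean_abundance(mat)
  expect_equal(ma$mean_abundance, c(0, 5))
  all_na <- intensity_tibble(matrix(c(NA_real_, 1, NA, 2, NA, 3), nrow = 2),
                             lines = c("A", "B", "C"), reps = c(1, 1, 1))
  expect_warning(res <- mean_abundance(all_na), "no detected value")
  expect_equal(res$protein_id, "P002")
})

test_that("F equals the one-way ANOVA statistic, balanced and unbalanced", {
  # hand example: groups {0,2} and {1,3} -> MSB = 1, MSW = 2
  mat <- intensity_tibble(matrix(c(0, 2, 1, 3), nrow = 1),
                          lines = c("A", "A", "B", "B"))
  expect_equal(f_value(mat)$f_value, 0.5)

  # random unbalanced data against stats::oneway.test / aov as oracle
  withr::with_seed(17, {
    for (i in 1:10) {
      v <- matrix(rnorm(12), nrow = 1)
      v[sample(12, 3)] <- NA
      lines <- rep(c("A", "B", "C", "D"), each = 3)
      mat <- intensity_tibble(v, lines = lines)
      fv <- f_value(mat, min_lines = 2, min_lines_with_reps = 1)
      keep <- !is.na(v[1, ])
      fit <- stats::anova(stats::lm(v[1, keep] ~ factor(lines[keep])))
      expect_equal(fv$f_value, fit$`F value`[1], tolerance = 1e-12)
    }
  })
})

test_that("F is invariant to shifting and positive rescaling of a protein", {
  withr::with_seed(9, {
    v <- matrix(rnorm(33), nrow = 1)
  })
  lines <- rep(sprintf("L%02d", 1:11), each = 3)
  f0 <- f_value(intensity_tibble(v, lines))$f_value
  expect_equal(f_value(intensity_tibble(v + 13.7, lines))$f_value, f0,
               tolerance = 1e-9)
  expect_equal(f_value(intensity_tibble(v * 0.031, lines))$f_value, f0,
               tolerance = 1e-9)
})

test_that("degenerate F cases are flagged, not silently dropped", {
  # all cell-line means equal, within-spread > 0 -> F = 0
  mat <- intensity_tibble(matrix(c(1, 3, 1, 3, 1, 3), nrow = 1),
                          lines = rep(c("A", "B", "C"), each = 2))
  expect_equal(f_value(mat)$f_value, 0)
  # zero within spread -> +Inf sentinel
  mat2 <- intensity_tibble(matrix(c(1, 1, 2, 2), nrow = 1),
                           lines = c("A", "A", "B", "B"))
  fv2 <- f_value(mat2)
  expect_equal(fv2$f_value, Inf)
  expect_equal(fv2$f_flag, "undefined_within")
  # single detected replicate everywhere -> insufficient replication
  mat3 <- intensity_tibble(matrix(c(1, 2, 3), nrow = 1),
                           lines = c("A", "B", "C"), reps = c(1, 1, 1))
  fv3 <- suppressMessages(f_value(mat3))
  expect_true(is.na(fv3$f_value))
  expect_equal(fv3$f_flag, "too_few_replicated_lines")
})

test_that("null F values follow the F(k-1, k(r-1)) reference distribution", {
  mat <- null_intensity_matrix(4000, 11, 3, seed = 101)
  fv <- f_value(mat)
  expect_gt(stats::ks.test(fv$f_value, stats::pf, 10, 22)$p.value, 0.01)
  expect_equal(mean(fv$f_value), 22 / 20, tolerance = 0.05)
})

test_that("permuted abundances break both confound correlations", {
  w <- small_world(n = 1200, seed = 77)
  f <- protein_features(w$intensities)
  withr::with_seed(1, {
    f$mean_abundance <- sample(f$mean_abundance)
  })
  cc <- confound_check(f)
  expect_true(all(abs(cc$estimate) < 0.1))
  expect_true(all(cc$p_value > 1e-4))
})

test_that("reference-set comparison recovers a planted low-variability set", {
  w <- small_world(n = 1500, seed = 55)
  f <- protein_features(w$intensities)
  truth <- w$truth$proteins
  low <- truth$protein_id[!truth$high_variability & truth$layer == "other"]
  high <- truth$protein_id[truth$high_variability & truth$layer == "other"]
  cmp <- compare_reference_sets(f, low, high)
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$direction, "lower")
  # identical sets show no difference
  cmp2 <- compare_reference_sets(f, low, low)
  expect_equal(cmp2$direction, "none")
  expect_error(compare_reference_sets(f, "absent_protein", high),
               "empty intersection")
})

test_that("tissue quartile sets follow the filter and quartile rules", {
  # 8 proteins, sds 1..8 after filters -> low = {sd 1,2}, high = {sd 7,8}
  base <- seq(0, 14, length.out = 8) * 100 + 1000
  v <- rbind(
    t(vapply(1:8, function(i) 50 + c(-1, 0, 1) * i, numeric(3)))
  )
  v <- v + base # high abundance, sd i per protein
  low_ab <- matrix(0.01, nrow = 8, ncol = 3) # below-average abundance rows
  mm <- intensity_tibble(rbind(v, low_ab), lines = c("T1", "T2", "T3"),
                         reps = c(1, 1, 1),
                         ids = sprintf("M%02d", 1:16))
  map <- tibble::tibble(source_id = sprintf("M%02d", 1:16),
                        target_id = sprintf("H%02d", 1:16))
  sets <- mouse_quartile_sets(mm, map, log_transform = FALSE)
  expect_setequal(sets$low, c("H01", "H02"))
  expect_setequal(sets$high, c("H07", "H08"))

  # a protein missing in one tissue is excluded
  v2 <- rbind(v, c(NA, 5000, 5000))
  mm2 <- intensity_tibble(v2, lines = c("T1", "T2", "T3"), reps = c(1, 1, 1),
                          ids = sprintf("M%02d", 1:9))
  map2 <- tibble::tibble(source_id = sprintf("M%02d", 1:9),
                         target_id = sprintf("H%02d", 1:9))
  sets2 <- mouse_quartile_sets(mm2, map2, log_transform = FALSE)
  expect_false("H09" %in% c(sets2$low, sets2$high))

  # random data: match brute-force sort-and-slice
  withr::with_seed(23, {
    vr <- matrix(abs(rnorm(40 * 5, 10, 3)), 40)
  })
  mmr <- intensity_tibble(vr, lines = paste0("T", 1:5), reps = rep(1, 5),
                          ids = sprintf("M%02d", 1:40))
  mapr <- tibble::tibble(source_id = sprintf("M%02d", 1:40),
                         target_id = sprintf("M%02d", 1:40))
  setsr <- mouse_quartile_sets(mmr, mapr, log_transform = FALSE)
  means <- rowMeans(vr)
  keep <- means > mean(means)
  sds <- apply(vr[keep, ], 1, sd)
  ids <- sprintf("M%02d", 1:40)[keep]
  qs <- quantile(sds, c(0.25, 0.75))
  expect_setequal(setsr$low, ids[sds <= qs[1]])
  expect_setequal(setsr$high, ids[sds >= qs[2]])
})
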