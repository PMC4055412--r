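toy_pathways <- function() {
  tibble::tibble(
    protein_id = c("r1", "r1", "k1", "amb", "amb", "lig", "med", "nn"),
    pathway_id = c("ST", "AP", "ST", "ST", "ST", "MB", "ST", "GE"),
    source = c("reactome", "reactome", "reactome", "reactome", "reactome",
               "signalink", "signalink", "reactome"),
    raw_class = c("receptor", "receptor", "kinase", "kinase",
                  "transcription_factor", "ligand", "mediator", "none")
  )
}

test_that("functional classes are unique or ambiguous; counts match a tally", {
  ann <- assign_functional_class(toy_pathways())
  cls <- setNames(ann$functional_class, ann$protein_id)
  expect_equal(cls[["r1"]], "receptor")
  expect_equal(cls[["amb"]], "ambiguous") # kinase + TF
  expect_equal(cls[["nn"]], "none")
  expect_equal(ann$pathway_count[ann$protein_id == "r1"], 2L)
  expect_true(ann$exclusive[ann$protein_id == "k1"])
  expect_error(assign_functional_class(
    dplyr::mutate(toy_pathways(), raw_class = "enzyme")), "unknown raw_class")

  # random tables: class counts equal a brute-force tally
  withr::with_seed(2, {
    tbl <- tibble::tibble(
      protein_id = sample(sprintf("p%02d", 1:40), 120, replace = TRUE),
      pathway_id = sample(c("A", "B", "C"), 120, replace = TRUE),
      source = "reactome",
      raw_class = sample(VALID_RAW_CLASSES, 120, replace = TRUE)
    )
  })
  ann2 <- assign_functional_class(tbl)
  brute <- vapply(split(tbl$raw_class, tbl$protein_id), function(cl) {
    cl <- setdiff(unique(cl), "none")
    if (length(cl) == 0) "none" else if (length(cl) == 1) cl else "ambiguous"
  }, "")
  expect_equal(setNames(ann2$functional_class, ann2$protein_id),
               brute[ann2$protein_id])
})

test_that("layer pooling follows the bow-tie mapping", {
  lay <- annotate_layers(toy_pathways())
  map <- setNames(lay$layer, lay$protein_id)
  expect_equal(map[["r1"]], "input")
  expect_equal(map[["k1"]], "transmission")
  expect_equal(map[["med"]], "transmission") # cofactor/mediator, no conflict
  expect_equal(map[["lig"]], "unassigned")   # ligands are never pooled
  expect_equal(map[["amb"]], "unassigned")   # conflicting classes
  # a mediator also annotated receptor is ambiguous, hence unassigned
  conflicted <- tibble::tibble(
    protein_id = "x", pathway_id = c("ST", "ST"),
    source = "signalink", raw_class = c("mediator", "receptor")
  )
  expect_equal(annotate_layers(conflicted)$layer, "unassigned")

  w <- small_world(n = 800, seed = 3)
  lay2 <- annotate_layers(w$pathways)
  truth <- w$truth$proteins
  merged <- dplyr::inner_join(lay2, truth, by = "protein_id")
  clean <- merged[merged$functional_class != "ambiguous" &
                    !merged$layer.y %in% "other", ]
  # non-ambiguous proteins land in their planted layer
  expect_true(all(clean$layer.x[clean$layer.y == "input"] %in%
                    c("input", "unassigned")))
  tally <- table(merged$layer.x)
  expect_equal(sum(tally), nrow(merged))
})

test_that("class-vs-complement test recovers a planted shift and calibrates", {
  withr::with_seed(101, {
    universe <- sprintf("u%03d", 1:200)
    feats <- tibble::tibble(
      protein_id = universe,
      score = c(rnorm(100, 1), rnorm(100, 0))
    )
  })
  cmp <- class_feature_test(feats, "score", members = universe[1:100])
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$direction, "higher")
  expect_error(class_feature_test(feats, "score", members = universe),
               "empty")

  # type-I: random membership is significant at roughly the nominal rate
  withr::with_seed(7, {
    hits <- replicate(400, {
      f <- tibble::tibble(protein_id = universe, score = rnorm(200))
      class_feature_test(f, "score",
                         members = sample(universe, 80))$p_value < 0.01
    })
  })
  expect_lte(sum(hits), 15) # ~4 expected at the 1% level over 400 runs
})

test_that("layer summary reports medians, IQRs and all pairwise tests", {
  w <- small_world(n = 1500, seed = 23)
  f <- protein_features(w$intensities)
  cons <- conservation_score(w$homology, w$tree, check_universe = FALSE)
  f <- dplyr::left_join(f, dplyr::select(cons, protein_id,
                                         conservation = score),
                        by = "protein_id")
  ls <- layer_feature_summary(f, annotate_layers(w$pathways))
  expect_s3_class(ls, "bowtie_layer_summary")
  expect_setequal(unique(ls$summary$layer),
                  c("input", "transmission", "output"))
  expect_equal(nrow(ls$comparisons), 3 * 3) # 3 features x 3 layer pairs
  # planted gradient: input more variable than transmission
  it <- ls$comparisons[ls$comparisons$feature == "log10_f" &
                         ls$comparisons$layer_a == "input" &
                         ls$comparisons$layer_b == "transmission", ]
  expect_equal(it$direction, "higher")
  # planted bell: transmission more conserved than input
  ct <- ls$comparisons[ls$comparisons$feature == "conservation" &
                         ls$comparisons$layer_a == "input" &
                         ls$comparisons$layer_b == "transmission", ]
  expect_equal(ct$direction, "lower")
  expect_equal(nrow(tidy(ls)), 9)
  expect_equal(glance(ls)$n_layers, 3L)
})

test_that("exclusive/multiple split reports fold ratios matching enumeration", {
  # 4-class toy: 8 proteins, multiple-pathway set of 4
  tbl <- tibble::tibble(
    protein_id = c("a", "b", "c", "d", "e", "e", "f", "f", "g", "g", "h", "h"),
    pathway_id = c("P1", "P1", "P1", "P1", "P1", "P2", "P1", "P2",
                   "P1", "P2", "P1", "P2"),
    source = "reactome",
    raw_class = c("kinase", "kinase", "receptor", "transcription_factor",
                  "kinase", "kinase", "kinase", "kinase",
                  "receptor", "receptor", "transcription_factor",
                  "transcription_factor")
  )
  feats <- tibble::tibble(protein_id = letters[1:8], conservation = 1:8 / 8,
                          log10_f = rnorm(8), mean_abundance = rnorm(8))
  res <- split_exclusive_multiple(tbl, feats)
  expect_setequal(res$exclusive, c("a", "b", "c", "d"))
  expect_setequal(res$multiple, c("e", "f", "g", "h"))
  # kinases: 4 of 8 overall; 2 observed among 4 multiple; expected 2 -> fold 1
  kin <- res$class_fold[res$class_fold$functional_class == "kinase", ]
  expect_equal(kin$observed, 2)
  expect_equal(kin$fold, 1)

  # single pathway: multiple set empty, comparisons skipped
  one <- dplyr::mutate(tbl, pathway_id = "P1") |> dplyr::distinct()
  expect_message(res1 <- split_exclusive_multiple(one, feats), "skipped")
  expect_length(res1$multiple, 0)
  expect_equal(nrow(res1$comparisons), 0)
})

test_that("multi-pathway proteins are planted more conserved via transmission", {
  w <- small_world(n = 2500, seed = 31)
  f <- protein_features(w$intensities)
  cons <- conservation_score(w$homology, w$tree, check_universe = FALSE)
  f <- dplyr::left_join(f, dplyr::select(cons, protein_id,
                                         conservation = score),
                        by = "protein_id")
  res <- split_exclusive_multiple(w$pathways, f)
  ccmp <- res$comparisons[res$comparisons$feature == "conservation", ]
  expect_lt(ccmp$p_value, 0.01)
  expect_equal(ccmp$direction, "lower") # exclusive less conserved
})

test_that("quantile bins have near-equal occupancy with ties in the lower bin", {
  b <- quantile_bin(1:10, 5)
  expect_equal(as.vector(table(b)), rep(2L, 5))
  expect_error(quantile_bin(rep(1, 10), 3), "distinct")
  expect_error(quantile_bin(c(1, 2), 5), "distinct")

  withr::with_seed(15, {
    for (i in 1:10) {
      x <- sample(round(rnorm(200), sample(0:1, 1)))
      k <- sample(2:8, 1)
      if (length(unique(x)) < k) next
      b <- quantile_bin(x, k)
      # all members of a tie group share one bin
      expect_true(all(tapply(b, x, function(v) length(unique(v)) == 1)))
      # per-bin occupancy deviates from the equal split by at most the
      # largest tie group (a straddling group moves whole to the lower bin)
      occ <- tabulate(b, k)
      expect_true(all(abs(occ - length(x) / k) <= max(max(table(x)), 1)))
      # against rank oracle: bin boundaries respect value order
      expect_true(all(diff(b[order(x)]) >= 0))
    }
  })
})
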