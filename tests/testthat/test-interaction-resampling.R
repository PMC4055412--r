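# a tiny fully controlled layer/feature/edge fixture
pair_fixture <- function() {
  layers <- tibble::tibble(
    protein_id = c("i1", "i2", "i3", "t1", "t2", "t3", "o1", "o2"),
    functional_class = c("receptor", "receptor", "receptor", "kinase",
                         "kinase", "kinase", "transcription_factor",
                         "transcription_factor"),
    layer = c("input", "input", "input", "transmission", "transmission",
              "transmission", "output", "output")
  )
  features <- tibble::tibble(
    protein_id = layers$protein_id,
    log10_f = c(2, 1.5, 1, 0.5, 0, -1, 0.2, -0.2)
  )
  edges <- tibble::tibble(
    protein_a = c("i1", "i2", "i3", "t1", "t2", "i1", "o1"),
    protein_b = c("t1", "t2", "t3", "o1", "o2", "i2", "o2")
  )
  list(layers = layers, features = features, edges = edges)
}

test_that("edge lists are canonical, deduplicated and loop-free", {
  raw <- tibble::tibble(a = c("x", "y", "y"), b = c("y", "x", "z"))
  el <- as_edge_list(raw)
  expect_equal(nrow(el), 2)
  expect_true(all(el$protein_a < el$protein_b))
  expect_error(as_edge_list(tibble::tibble(a = "x", b = "x")), "self-loop")
})

test_that("pair sampling is seed-reproducible and respects category support", {
  fx <- pair_fixture()
  s1 <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 50,
                     seed = 7)
  s2 <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 50,
                     seed = 7)
  expect_identical(tibble::as_tibble(s1), tibble::as_tibble(s2))
  expect_true(attr(s1, "replace")) # only 3 eligible IT edges
  # support is exactly the 3 IT edges
  expect_setequal(unique(paste(s1$protein_a, s1$protein_b)),
                  c("i1 t1", "i2 t2", "i3 t3"))
  # every sampled pair keeps the layer constraint (input in column a)
  lay <- setNames(fx$layers$layer, fx$layers$protein_id)
  expect_true(all(lay[s1$protein_a] == "input"))
  expect_true(all(lay[s1$protein_b] == "transmission"))

  to <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-TO", n = 20,
                     seed = 1)
  expect_setequal(unique(paste(to$protein_a, to$protein_b)),
                  c("t1 o1", "t2 o2"))
  w <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-W", n = 20,
                    seed = 1)
  expect_setequal(unique(paste(w$protein_a, w$protein_b)),
                  c("i1 i2", "o1 o2"))
})

test_that("Rand-IT pairs are input-transmission non-edges", {
  fx <- pair_fixture()
  r <- sample_pairs(fx$edges, fx$layers, fx$features, "Rand-IT", n = 200,
                    seed = 3)
  lay <- setNames(fx$layers$layer, fx$layers$protein_id)
  expect_true(all(lay[r$protein_a] == "input"))
  expect_true(all(lay[r$protein_b] == "transmission"))
  keys <- paste(pmin(r$protein_a, r$protein_b),
                pmax(r$protein_a, r$protein_b))
  edge_keys <- paste(fx$edges$protein_a, fx$edges$protein_b)
  expect_false(any(keys %in% edge_keys))
})

test_that("sampling is uniform over the eligible pair set", {
  fx <- pair_fixture()
  s <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 6000,
                    seed = 21)
  counts <- table(paste(s$protein_a, s$protein_b))
  gof <- stats::chisq.test(counts, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.01)
})

test_that("absolute variability differences are plain arithmetic", {
  fx <- pair_fixture()
  s <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 30,
                    seed = 2)
  d <- abs_variability_diff(s)
  expect_length(d, 30)
  expect_equal(d, abs(s$log_f_a - s$log_f_b))
  # pair (logF 2, logF -1) -> 3
  i1t3 <- which(s$protein_a == "i1")[1]
  expect_equal(abs(2 - 0.5),
               d[i1t3]) # i1 (2) always pairs t1 (0.5) in this fixture
})

test_that("permuting links preserves endpoint multisets and layer sides", {
  fx <- pair_fixture()
  s <- sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 100,
                    seed = 5)
  p <- permute_links(s, seed = 9)
  expect_equal(attr(p, "category"), "Perm-IT")
  expect_equal(sort(p$protein_a), sort(s$protein_a))
  expect_equal(sort(p$protein_b), sort(s$protein_b))
  expect_identical(p$protein_a, s$protein_a) # input side kept in order
  lay <- setNames(fx$layers$layer, fx$layers$protein_id)
  expect_true(all(lay[p$protein_b] == "transmission"))
  expect_error(permute_links(p, seed = 1), "PPI-IT")

  # n = 2 distinct pairs: identity and swap both occur over seeds
  s2 <- structure(
    tibble::tibble(protein_a = c("i1", "i2"), protein_b = c("t1", "t2"),
                   log_f_a = c(2, 1.5), log_f_b = c(0.5, 0)),
    category = "PPI-IT", seed = 0, replace = FALSE,
    class = c("pair_sample", class(tibble::tibble()))
  )
  arr <- vapply(1:40, function(sd) {
    paste(permute_links(s2, seed = sd)$protein_b, collapse = "")
  }, "")
  expect_setequal(unique(arr), c("t1t2", "t2t1"))
})

test_that("planted assortative wiring yields PPI-IT > Rand-IT and Perm-IT", {
  w <- generate_world(world_config(n_proteins = 2500, seed = 61))
  f <- protein_features(w$intensities)
  lay <- annotate_layers(w$pathways)
  it <- sample_pairs(w$edges, lay, f, "PPI-IT", n = 1000, seed = 1)
  rit <- sample_pairs(w$edges, lay, f, "Rand-IT", n = 1000, seed = 2)
  perm <- permute_links(it, seed = 3)
  c1 <- compare_pair_distributions(it, rit)
  c2 <- compare_pair_distributions(it, perm)
  expect_equal(c1$direction, "higher")
  expect_lt(c1$p_value, 1e-4)
  expect_equal(c2$direction, "higher")
  expect_lt(c2$p_value, 1e-4)
  # identical distributions -> no direction
  c3 <- compare_pair_distributions(it, it)
  expect_equal(c3$direction, "none")
})

test_that("relabeling proteins leaves the sampled |d| distribution intact", {
  fx <- pair_fixture()
  d0 <- abs_variability_diff(
    sample_pairs(fx$edges, fx$layers, fx$features, "PPI-IT", n = 500,
                 seed = 77))
  relabel <- function(x) paste0("z_", x)
  fx2 <- list(
    layers = dplyr::mutate(fx$layers, protein_id = relabel(protein_id)),
    features = dplyr::mutate(fx$features, protein_id = relabel(protein_id)),
    edges = dplyr::mutate(fx$edges, protein_a = relabel(protein_a),
                          protein_b = relabel(protein_b))
  )
  d1 <- abs_variability_diff(
    sample_pairs(fx2$edges, fx2$layers, fx2$features, "PPI-IT", n = 500,
                 seed = 77))
  expect_equal(sort(d0), sort(d1))
})
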