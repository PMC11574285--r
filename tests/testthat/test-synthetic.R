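test_that("taxonomy nesting is consistent and shape-driven", {
  cfg <- synthetic_config(
    n_cells_scrna = 10, n_cells_spatial = 10,
    taxonomy_shape = c(n_class = 2, n_subclass_per_class = 1,
                       n_supertype_per_subclass = 1, n_cluster_per_supertype = 1),
    seed = 3)
  cells <- generate_taxonomy(cfg)
  expect_equal(nrow(cells), 10)
  expect_equal(length(unique(cfg$taxonomy$cluster)), 2)
  # each cluster maps to exactly one supertype/subclass/class
  for (lv in c("supertype", "subclass", "class")) {
    map <- unique(cells[, c("cluster", lv)])
    expect_false(anyDuplicated(map$cluster) > 0)
  }
})

test_that("generation is a pure function of the seed", {
  cfg <- synthetic_config(n_cells_scrna = 200, n_cells_spatial = 200, seed = 11)
  expect_identical(generate_taxonomy(cfg), generate_taxonomy(cfg))
  cells <- generate_taxonomy(cfg)
  expect_identical(generate_expression(cells, cfg), generate_expression(cells, cfg))
  expect_identical(generate_spatial(cfg), generate_spatial(cfg))
})

test_that("cluster assignment is multinomial-uniform", {
  cfg <- synthetic_config(
    n_cells_scrna = 10000, n_cells_spatial = 10,
    taxonomy_shape = c(n_class = 3, n_subclass_per_class = 2,
                       n_supertype_per_subclass = 2, n_cluster_per_supertype = 2),
    seed = 5)
  cells <- generate_taxonomy(cfg)
  k <- nrow(cfg$taxonomy)
  counts <- table(factor(cells$cluster, levels = cfg$taxonomy$cluster))
  expected <- 10000 / k
  sd <- sqrt(10000 * (1 / k) * (1 - 1 / k))
  expect_true(all(abs(counts - expected) <= 4 * sd))
})

test_that("degenerate detection probabilities yield exact prevalences", {
  shape <- c(n_class = 2, n_subclass_per_class = 1,
             n_supertype_per_subclass = 1, n_cluster_per_supertype = 1)
  genes <- htr_genes()
  for (p in c(0, 1)) {
    cfg <- synthetic_config(
      n_cells_scrna = 300, n_cells_spatial = 10, taxonomy_shape = shape,
      detection_prob = matrix(p, 2, length(genes)), seed = 9)
    cells <- generate_taxonomy(cfg)
    mask <- detect(generate_expression(cells, cfg))
    expect_equal(unname(colMeans(mask)) * 100, rep(100 * p, length(genes)))
  }
})

test_that("planted detection probability is recovered within binomial error", {
  shape <- c(n_class = 1, n_subclass_per_class = 1,
             n_supertype_per_subclass = 1, n_cluster_per_supertype = 1)
  genes <- htr_genes()
  dp <- matrix(0, 1, length(genes))
  dp[1, 1] <- 0.5
  cfg <- synthetic_config(n_cells_scrna = 10000, n_cells_spatial = 10,
                          taxonomy_shape = shape, detection_prob = dp, seed = 21)
  cells <- generate_taxonomy(cfg)
  mask <- detect(generate_expression(cells, cfg))
  # 3 binomial SEs of p = 0.5 at n = 10,000 is 1.5 percentage points
  expect_lt(abs(100 * mean(mask[, 1]) - 50), 1.5)
  expect_equal(sum(mask[, -1]), 0)
})

test_that("detected amounts sit strictly above threshold, undetected at zero", {
  cfg <- synthetic_config(n_cells_scrna = 500, n_cells_spatial = 500, seed = 2)
  cells <- generate_taxonomy(cfg)
  expr <- generate_expression(cells, cfg)
  thr <- thresholds()
  expect_true(all(expr[expr > 0] > thr$detection_scrna))
  expect_true(all(expr[expr <= thr$detection_scrna] == 0))
  sp <- generate_spatial(cfg)
  for (g in cfg$panel_genes) {
    v <- sp[[g]]
    expect_true(all(v[v > 0] > thr$detection_spatial))
  }
})

test_that("spatial table carries only panel genes and valid parcellation", {
  cfg <- synthetic_config(n_cells_scrna = 50, n_cells_spatial = 400, seed = 4)
  sp <- generate_spatial(cfg)
  missing_genes <- setdiff(cfg$genes, cfg$panel_genes)
  expect_true(all(cfg$panel_genes %in% names(sp)))
  expect_false(any(missing_genes %in% names(sp)))
  # structure nests in exactly one division
  map <- unique(sp[, c("structure", "division")])
  expect_equal(anyDuplicated(map$structure), 0L)
  # section label is a deterministic function of the AP coordinate
  rng <- cfg$section_axis_range
  bin <- pmin(floor((sp$ap_coordinate - rng[1]) / diff(rng) * cfg$n_sections),
              cfg$n_sections - 1) + 1
  expect_identical(sp$section_label, sprintf("sec%02d", bin))
})

test_that("spatial scaling shrinks detection prevalence proportionally", {
  shape <- c(n_class = 1, n_subclass_per_class = 1,
             n_supertype_per_subclass = 1, n_cluster_per_supertype = 1)
  dp <- matrix(0.8, 1, length(htr_genes()))
  cfg <- synthetic_config(n_cells_scrna = 10, n_cells_spatial = 20000,
                          taxonomy_shape = shape, detection_prob = dp,
                          spatial_scale = 0.5, seed = 13)
  sp <- generate_spatial(cfg)
  g <- cfg$panel_genes[1]
  p_hat <- mean(sp[[g]] > thresholds()$detection_spatial)
  expect_lt(abs(p_hat - 0.4), 4 * sqrt(0.4 * 0.6 / 20000))
})

test_that("ground truth matches the enrichment definition and config", {
  cfg <- synthetic_config(n_cells_scrna = 10, n_cells_spatial = 10, seed = 8)
  gt <- ground_truth(cfg)
  expect_equal(gt$planted_prevalence, 100 * cfg$detection_prob)
  frac <- thresholds()$enrichment_fraction / 100
  for (g in cfg$genes) {
    expect_setequal(gt$planted_enriched[[g]],
                    rownames(cfg$detection_prob)[cfg$detection_prob[, g] >= frac])
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(taxonomy_shape = c(n_class = 0,
    n_subclass_per_class = 1, n_supertype_per_subclass = 1,
    n_cluster_per_supertype = 1)), "positive integers")
  expect_error(synthetic_config(panel_genes = c("NotAGene")), "subset")
  expect_error(synthetic_config(
    n_cells_scrna = 10, n_cells_spatial = 10,
    detection_prob = matrix(2, 40, 14)), "\\[0, 1\\]")
})
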