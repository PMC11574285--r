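make_scrna_fixture <- function(probs, n_per_cluster, gene = "Htr1a", seed = 1) {
  k <- length(probs)
  n <- k * n_per_cluster
  cells <- tibble::tibble(
    cell_label = sprintf("c%05d", seq_len(n)),
    class = "C01", subclass = "S01", supertype = "T01",
    cluster = rep(sprintf("cl%02d", seq_len(k)), each = n_per_cluster))
  withr::with_seed(seed, {
    det <- runif(n) < rep(probs, each = n_per_cluster)
  })
  mask <- matrix(det, ncol = 1, dimnames = list(cells$cell_label, gene))
  list(cells = cells, mask = mask)
}

test_that("enrichment keeps exactly the clusters above the threshold", {
  fx <- make_scrna_fixture(c(1, 0, 0.9, 0.8, 0.5, 0.1), 200, seed = 2)
  enr <- find_enriched_clusters(fx$mask, fx$cells, "Htr1a")
  # 100% retained, 0% excluded, and {0.9, 0.8} in with margin >> sampling error
  expect_setequal(enr$clusters, c("cl01", "cl03", "cl04"))
  expect_true(all(enr$in_cluster_prevalence >= 70))
  expect_error(find_enriched_clusters(fx$mask, fx$cells, "NotAGene"), "absent")

  # enriched_fraction: percent of detecting cells inside retained clusters
  grp <- fx$cells$cluster
  det <- fx$mask[, 1]
  ref <- 100 * sum(det & grp %in% enr$clusters) / sum(det)
  expect_equal(enr$enriched_fraction, ref)
})

test_that("raising the enrichment threshold never adds clusters", {
  fx <- make_scrna_fixture(seq(0.05, 0.95, length.out = 8), 100, seed = 5)
  prev_set <- NULL
  for (cut in c(30, 50, 70, 90)) {
    enr <- find_enriched_clusters(fx$mask, fx$cells, "Htr1a",
                                  thresholds(enrichment_fraction = cut))
    if (!is.null(prev_set)) expect_true(all(enr$clusters %in% prev_set))
    prev_set <- enr$clusters
  }
})

test_that("cross-referencing filters spatial cells by cluster label", {
  cfg <- synthetic_config(n_cells_scrna = 100, n_cells_spatial = 500, seed = 3)
  sp <- generate_spatial(cfg)
  enr <- structure(list(gene = "Htr6", clusters = character(0)),
                   class = "enriched_clusters")
  expect_equal(nrow(cross_reference(enr, sp)), 0)

  enr$clusters <- unique(sp$cluster)
  expect_equal(nrow(cross_reference(enr, sp)), nrow(sp))

  enr$clusters <- unique(sp$cluster)[1:5]
  got <- cross_reference(enr, sp)
  expect_equal(as.data.frame(got),
               as.data.frame(sp[sp$cluster %in% enr$clusters, ]))
})

test_that("regional prevalence matches the per-region ratio oracle in both modes", {
  cfg <- synthetic_config(n_cells_scrna = 100, n_cells_spatial = 800, seed = 7)
  sp <- generate_spatial(cfg)
  enr <- structure(list(gene = "Htr1a", clusters = unique(sp$cluster)[1:10]),
                   class = "enriched_clusters")

  got <- prevalence_by_parcellation(sp, "division", "crossref", enr)
  flag <- sp$cluster %in% enr$clusters
  ref <- oracle_region_prevalence(flag, sp$division)
  expect_equal(setNames(got$prevalence, got$region), ref[got$region])

  gotd <- prevalence_by_parcellation(sp, "structure", "direct", gene = "Htr1a")
  flagd <- sp$Htr1a > thresholds()$detection_spatial
  refd <- oracle_region_prevalence(flagd, sp$structure)
  expect_equal(setNames(gotd$prevalence, gotd$region), refd[gotd$region])

  # ranked descending
  expect_true(all(diff(got$prevalence) <= 0))
  expect_error(prevalence_by_parcellation(sp, "division", "direct", gene = "Htr6"),
               "panel")
})

test_that("crossref regional prevalence ignores the spatial panel entirely", {
  cfg <- synthetic_config(n_cells_scrna = 100, n_cells_spatial = 600, seed = 9)
  sp <- generate_spatial(cfg)
  enr <- structure(list(gene = "Htr5b", clusters = unique(sp$cluster)[1:8]),
                   class = "enriched_clusters")
  with_panel <- prevalence_by_parcellation(sp, "division", "crossref", enr)
  stripped <- sp[, setdiff(names(sp), htr_panel_genes())]
  without_panel <- prevalence_by_parcellation(stripped, "division", "crossref", enr)
  expect_equal(with_panel, without_panel)
})

test_that("division prevalence is the count-weighted mean of its structures", {
  cfg <- synthetic_config(n_cells_scrna = 100, n_cells_spatial = 700, seed = 11)
  sp <- generate_spatial(cfg)
  enr <- structure(list(gene = "Htr2a", clusters = unique(sp$cluster)[1:12]),
                   class = "enriched_clusters")
  by_div <- prevalence_by_parcellation(sp, "division", "crossref", enr)
  by_str <- prevalence_by_parcellation(sp, "structure", "crossref", enr)
  for (d in by_div$region) {
    sub <- by_str[by_str$division == d, ]
    pooled <- sum(sub$prevalence * sub$n_cells) / sum(sub$n_cells)
    expect_equal(by_div$prevalence[by_div$region == d], pooled)
  }
})

test_that("crossref and direct modes agree on deterministic planted data", {
  genes <- htr_genes()
  dp <- matrix(0, 4, length(genes), dimnames = NULL)
  dp[c(1, 3), match("Htr1a", genes)] <- 1  # clusters 1 and 3 always express
  cfg <- synthetic_config(
    n_cells_scrna = 2000, n_cells_spatial = 2000,
    taxonomy_shape = c(n_class = 4, n_subclass_per_class = 1,
                       n_supertype_per_subclass = 1, n_cluster_per_supertype = 1),
    detection_prob = dp, seed = 13)
  cells <- generate_taxonomy(cfg)
  mask <- detect(generate_expression(cells, cfg))
  sp <- generate_spatial(cfg)
  enr <- find_enriched_clusters(mask, cells, "Htr1a")
  a <- prevalence_by_parcellation(sp, "structure", "crossref", enr)
  b <- prevalence_by_parcellation(sp, "structure", "direct", gene = "Htr1a")
  expect_equal(a, b)
})

test_that("cross-dataset concordance recovers exact linear relations", {
  prev <- tibble::tibble(group = paste0("C", 1:6), gene = "Htr1a",
                         prevalence = c(5, 10, 20, 40, 60, 80), n_cells = 10)
  fit <- class_concordance(prev, prev)
  expect_equal(fit$slope, 1)
  expect_equal(fit$r_squared, 1)

  half <- prev
  half$prevalence <- prev$prevalence * 0.5
  fit2 <- class_concordance(prev, half)
  expect_equal(fit2$slope, 0.5)
  expect_equal(fit2$intercept, 0)
  expect_equal(fit2$r_squared, 1)
  expect_error(class_concordance(prev[1:2, ], prev[1:2, ]), ">= 3")
})

test_that("AP profiles match the per-section oracle and order sections", {
  cfg <- synthetic_config(n_cells_scrna = 100, n_cells_spatial = 900, seed = 15)
  sp <- generate_spatial(cfg)
  enr <- structure(list(gene = "Htr4", clusters = unique(sp$cluster)[1:10]),
                   class = "enriched_clusters")
  prof <- ap_profile(sp, "crossref", enr, "Htr4")
  flag <- sp$cluster %in% enr$clusters
  ref <- oracle_ap_profile(flag, sp$section_label, sp$ap_coordinate)
  expect_equal(prof$section_label, ref$section_label)
  expect_equal(prof$prevalence, unname(ref$prevalence))
  expect_true(all(diff(prof$ap) > 0))

  # subset confined to one section -> single nonzero section
  one_sec <- sp$section_label == "sec03"
  sp2 <- sp
  sp2$cluster <- ifelse(one_sec, "clX", "clY")
  enr2 <- structure(list(gene = "Htr4", clusters = "clX"),
                    class = "enriched_clusters")
  prof2 <- ap_profile(sp2, "crossref", enr2)
  expect_true(all(prof2$prevalence[prof2$section_label != "sec03"] == 0))
  expect_gt(prof2$prevalence[prof2$section_label == "sec03"], 0)
})

test_that("top-section selection follows the peak + spacing rule", {
  prof <- tibble::tibble(
    section_label = sprintf("s%02d", 1:9),
    ap = 1:9,
    prevalence = c(1, 5, 1, 2, 8, 2, 1, 4, 1),
    n_cells = 100, mean_amount = NA_real_)
  # strictly unimodal, k=1 -> the mode
  expect_equal(as.character(select_top_sections(prof, k = 1, min_spacing = 0)),
               "s05")
  # two equal peaks closer than min_spacing -> only one retained
  prof2 <- prof
  prof2$prevalence <- c(1, 8, 8, 1, 1, 1, 1, 1, 1)
  got <- select_top_sections(prof2, k = 2, min_spacing = 2)
  expect_equal(sum(as.character(got) %in% c("s02", "s03")), 1)

  # random profiles match the exhaustive-enumeration oracle
  for (seed in 1:8) {
    withr::with_seed(seed, {
      p <- round(runif(12, 0, 50), 1)
    })
    profr <- tibble::tibble(section_label = sprintf("s%02d", 1:12),
                            ap = 1:12, prevalence = p,
                            n_cells = 50, mean_amount = NA_real_)
    for (k in c(2, 4)) {
      got <- select_top_sections(profr, k = k, min_spacing = 2)
      ref <- oracle_top_sections(p, 1:12, profr$section_label, k, 2)
      expect_equal(as.character(got), ref)
    }
  }
})
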