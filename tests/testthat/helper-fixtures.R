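# Fixtures are built in code: random masks/matrices with seeded RNG and
# hand-built tiny cell tables.

rand_mask <- function(n, genes = htr_genes(), p = 0.3, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * length(genes)) < p, nrow = n,
                dimnames = list(sprintf("cell_%04d", seq_len(n)), genes))
    m
  })
}

rand_expr <- function(n, genes = htr_genes(), seed = 1, max = 8) {
  withr::with_seed(seed, {
    matrix(runif(n * length(genes), 0, max), nrow = n,
           dimnames = list(sprintf("cell_%04d", seq_len(n)), genes))
  })
}

# Minimal hand-built cell table over `n` cells and `g` groups at every level.
tiny_cells <- function(n, n_groups = 4, seed = 1) {
  withr::with_seed(seed, {
    grp <- sample(n_groups, n, replace = TRUE)
    tibble::tibble(
      cell_label = sprintf("cell_%04d", seq_len(n)),
      class = sprintf("C%02d", grp),
      subclass = sprintf("S%02d", grp),
      supertype = sprintf("T%02d", grp),
      cluster = sprintf("cl%02d", sample(2 * n_groups, n, replace = TRUE)),
      neighborhood = sprintf("NB%d", ((grp - 1) %% 3) + 1),
      neurotransmitter = sample(c("Glut", "Gaba", "None"), n, replace = TRUE)
    )
  })
}

# Config with planted single-gene class profiles: class i detects only
# gene i (deterministically), all other genes silent.
disjoint_profile_config <- function(n_cells, n_classes = 10, seed = 1) {
  genes <- htr_genes()
  dp <- matrix(0, nrow = n_classes, ncol = length(genes))
  dp[cbind(seq_len(n_classes), seq_len(n_classes))] <- 1
  synthetic_config(
    n_cells_scrna = n_cells, n_cells_spatial = 100,
    taxonomy_shape = c(n_class = n_classes, n_subclass_per_class = 1,
                       n_supertype_per_subclass = 1, n_cluster_per_supertype = 1),
    genes = genes, panel_genes = htr_panel_genes(),
    detection_prob = dp, seed = seed
  )
}
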