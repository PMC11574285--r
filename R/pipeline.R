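# One validated configuration object drives the whole pipeline; each
# run_* step reads the tables named in the config, runs the corresponding
# module, and writes tidy CSV/JSON outputs plus a manifest recording the
# config hash and package version, so every run is reproducible from its
# logged hash and seed.

pipeline_config_keys <- c(
  "cell_table", "expression", "spatial", "membership",
  "thresholds", "decoder", "family_map", "genes", "panel_genes",
  "synthetic", "top_k_groups", "top_k_sections", "seed"
)

#' Pipeline configuration
#'
#' Single source of truth for an analysis run: input table paths, the
#' detection/enrichment thresholds, the decoder specification, the family
#' map, gene and panel lists, report options and the seed. Defaults equal
#' the reference analysis values (3.5 / 0.3 / 70%, 5 folds, 200 trees,
#' depth 10, 10,000 attribution rows, top-10 groups, top-4 sections).
#' Unknown keys are rejected with a named error.
#'
#' @param cell_table,expression,spatial,membership Input file paths
#'   (membership optional).
#' @param thresholds A [thresholds()] object.
#' @param decoder A [decoder_spec()].
#' @param family_map A family map, see [htr_family_map()].
#' @param genes,panel_genes Gene lists.
#' @param synthetic Optional [synthetic_config()] used by
#'   [run_simulate()].
#' @param top_k_groups,top_k_sections Report options.
#' @param seed Integer seed.
#' @param ... Unknown keys — always an error naming them.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(cell_table = NULL, expression = NULL,
                            spatial = NULL, membership = NULL,
                            thresholds = htrmap::thresholds(),
                            decoder = decoder_spec(),
                            family_map = htr_family_map(),
                            genes = htr_genes(),
                            panel_genes = htr_panel_genes(),
                            synthetic = NULL,
                            top_k_groups = 10, top_k_sections = 4,
                            seed = 1L, ...) {
  extra <- list(...)
  if (length(extra) > 0) {
    stop("unknown configuration keys: ",
         paste(names(extra), collapse = ", "), call. = FALSE)
  }
  stopifnot(inherits(thresholds, "htr_thresholds"),
            inherits(decoder, "decoder_spec"),
            is_count(top_k_groups), is_count(top_k_sections))
  if (!all(panel_genes %in% genes)) {
    stop("panel_genes must be a subset of genes", call. = FALSE)
  }
  structure(
    list(cell_table = cell_table, expression = expression,
         spatial = spatial, membership = membership,
         thresholds = thresholds, decoder = decoder,
         family_map = family_map, genes = genes,
         panel_genes = panel_genes, synthetic = synthetic,
         top_k_groups = as.integer(top_k_groups),
         top_k_sections = as.integer(top_k_sections),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

write_manifest <- function(config, out_dir, step) {
  manifest <- list(
    step = step,
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("htrmap"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(step, "_manifest.json")),
                       auto_unbox = TRUE)
  invisible(manifest)
}

load_scrna <- function(config) {
  cells <- read_cell_table(config$cell_table)
  expr <- read_expression_matrix(config$expression)
  list(cells = cells, expr = expr,
       mask = detect(expr, config$thresholds, "scrna"))
}

#' Simulate the paired datasets to disk
#'
#' Generates the scRNA-seq-like cell table and expression matrix, the
#' spatial table, and the ground-truth sidecar from `config$synthetic`,
#' writes them as CSV/JSON under `out_dir`, and returns a
#' [pipeline_config()] whose input paths point at the written files.
#'
#' @param config A [pipeline_config()] with a non-NULL `synthetic` entry.
#' @param out_dir Output directory (created if needed).
#' @return An updated `pipeline_config`, invisibly usable for the other
#'   steps.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"),
            inherits(config$synthetic, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- config$synthetic
  cells <- generate_taxonomy(sc)
  expr <- generate_expression(cells, sc, config$thresholds)
  spatial <- generate_spatial(sc, config$thresholds)
  truth <- ground_truth(sc, config$thresholds)
  paths <- list(
    cell_table = file.path(out_dir, "cells.csv"),
    expression = file.path(out_dir, "expression.csv"),
    spatial = file.path(out_dir, "spatial.csv"),
    truth = file.path(out_dir, "ground_truth.json")
  )
  write_cell_table(cells, paths$cell_table)
  write_expression_matrix(expr, paths$expression)
  write_spatial_table(spatial, paths$spatial)
  write_ground_truth(truth, paths$truth)
  write_manifest(config, out_dir, "simulate")
  config$cell_table <- paths$cell_table
  config$expression <- paths$expression
  config$spatial <- paths$spatial
  config
}

#' Prevalence profiling step
#'
#' Writes the per-group prevalence table, the any-gene prevalence, and
#' the prevalence-amount shared variance for one grouping level.
#'
#' @param config A [pipeline_config()] with input paths set.
#' @param out_dir Output directory.
#' @param level Grouping column (default `"class"`).
#' @return The prevalence tibble, invisibly.
#' @export
run_profile <- function(config, out_dir, level = "class") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- load_scrna(config)
  prev <- prevalence_by_group(d$mask, d$cells, level)
  readr::write_csv(prev, file.path(out_dir, paste0("prevalence_", level, ".csv")))
  scalars <- list(
    level = level,
    prevalence_any = prevalence_any(d$mask),
    prevalence_amount_r2 = prevalence_amount_r2(d$expr, d$mask)
  )
  jsonlite::write_json(scalars, file.path(out_dir, "profile_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(config, out_dir, "profile")
  invisible(prev)
}

#' Co-localization step
#'
#' Writes the co-localization matrix, the co-transcription count
#' distribution, and the gene-gene expression correlation matrix.
#'
#' @inheritParams run_profile
#' @return The co-localization matrix, invisibly.
#' @export
run_coloc <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- load_scrna(config)
  cm <- coloc_matrix(d$mask)
  readr::write_csv(tibble::as_tibble(cm, rownames = "gene"),
                   file.path(out_dir, "coloc_matrix.csv"))
  readr::write_csv(n_receptors_distribution(d$mask),
                   file.path(out_dir, "n_receptors.csv"))
  readr::write_csv(tibble::as_tibble(correlation_matrix(d$expr), rownames = "gene"),
                   file.path(out_dir, "correlation_matrix.csv"))
  write_manifest(config, out_dir, "coloc")
  invisible(cm)
}

#' Decoding step
#'
#' Cross-validated decoding of `level` from the boolean detection
#' profiles; writes accuracy scalars (JSON), the normalized confusion
#' matrix, the per-class report, and the attribution matrix (CSV).
#'
#' @inheritParams run_profile
#' @param level Target metadata column (default `"neurotransmitter"`).
#' @return The `decoding_result`, invisibly.
#' @export
run_decode <- function(config, out_dir, level = "neurotransmitter") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- load_scrna(config)
  ft <- make_feature_table(d$mask, d$cells, level)
  res <- run_decoder(ft$features, ft$labels, config$decoder)
  shap <- attribution_matrix(ft$features, ft$labels, config$decoder)
  jsonlite::write_json(
    list(level = level,
         mean_balanced_accuracy = res$mean_balanced_accuracy,
         per_fold = res$per_fold,
         chance_level = res$chance_level),
    file.path(out_dir, "decoding_summary.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(tibble::as_tibble(res$confusion, rownames = "true_label"),
                   file.path(out_dir, "confusion_matrix.csv"))
  readr::write_csv(res$per_class, file.path(out_dir, "per_class_report.csv"))
  readr::write_csv(tibble::as_tibble(shap, rownames = "class"),
                   file.path(out_dir, "attribution_matrix.csv"))
  write_manifest(config, out_dir, "decode")
  invisible(res)
}

#' Effector-family step
#'
#' Assigns primary families and writes the per-group composition table.
#'
#' @inheritParams run_profile
#' @param level Grouping column (default `"neighborhood"`).
#' @return The composition tibble, invisibly.
#' @export
run_effectors <- function(config, out_dir, level = "neighborhood") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- load_scrna(config)
  fs <- family_sums(d$expr, config$family_map)
  comp <- family_composition(primary_family(fs), d$cells, level)
  readr::write_csv(comp, file.path(out_dir, paste0("family_composition_", level, ".csv")))
  write_manifest(config, out_dir, "effectors")
  invisible(comp)
}

#' Spatial-mapping step for one gene
#'
#' Finds enriched clusters, cross-references them into the spatial
#' dataset (or uses direct spatial detection), and writes the regional
#' rankings, the AP profile with its top sections, the cross-modal
#' concordance fit, and the enriched-cluster summary.
#'
#' @inheritParams run_profile
#' @param gene Gene of interest.
#' @param mode `"crossref"` (default) or `"direct"`.
#' @return List of the computed objects, invisibly.
#' @export
run_spatial <- function(config, out_dir, gene, mode = c("crossref", "direct")) {
  mode <- match.arg(mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  d <- load_scrna(config)
  spatial <- read_spatial_table(config$spatial)
  enr <- find_enriched_clusters(d$mask, d$cells, gene, config$thresholds)
  gene_arg <- if (mode == "direct" || gene %in% names(spatial)) gene else NULL
  by_div <- prevalence_by_parcellation(spatial, "division", mode, enr, gene_arg,
                                       config$thresholds)
  by_struct <- prevalence_by_parcellation(spatial, "structure", mode, enr, gene_arg,
                                          config$thresholds,
                                          top_k = config$top_k_groups)
  prof <- ap_profile(spatial, mode, enr, gene_arg, config$thresholds)
  top_sections <- select_top_sections(prof, k = config$top_k_sections)

  conc <- NULL
  if (gene %in% names(spatial)) {
    prev_sc <- prevalence_by_group(d$mask[, gene, drop = FALSE], d$cells, "class")
    sp_expr <- as.matrix(spatial[, gene, drop = FALSE])
    rownames(sp_expr) <- spatial$cell_label
    sp_mask <- detect(sp_expr, config$thresholds, "spatial")
    prev_sp <- prevalence_by_group(sp_mask, spatial, "class")
    conc <- class_concordance(prev_sc, prev_sp, gene)
  }

  readr::write_csv(by_div, file.path(out_dir, paste0(gene, "_division.csv")))
  readr::write_csv(by_struct, file.path(out_dir, paste0(gene, "_structure.csv")))
  readr::write_csv(prof, file.path(out_dir, paste0(gene, "_ap_profile.csv")))
  jsonlite::write_json(
    list(gene = gene, mode = mode,
         enriched_clusters = enr$clusters,
         enriched_fraction = enr$enriched_fraction,
         top_sections = as.character(top_sections),
         concordance = conc),
    file.path(out_dir, paste0(gene, "_spatial_summary.json")),
    auto_unbox = TRUE, digits = NA)
  write_manifest(config, out_dir, "spatial")
  invisible(list(enriched = enr, by_division = by_div,
                 by_structure = by_struct, profile = prof,
                 top_sections = top_sections, concordance = conc))
}
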