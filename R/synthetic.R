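#' Configuration for the paired synthetic dataset generator
#'
#' Builds the single configuration object that drives generation of a
#' scRNA-seq-like cell table + expression matrix and a MERFISH-like spatial
#' cell table sharing the same cluster vocabulary. The generator plants a
#' known per-cluster Bernoulli detection probability for every gene, so
#' every downstream statistic (prevalence, enrichment, decoding signal,
#' cross-modal slope) has a recoverable ground truth.
#'
#' The taxonomy is nested exactly like the reference atlas taxonomy:
#' class > subclass > supertype > cluster, with every cluster mapping to
#' exactly one parent at each level. Defaults are desk-scale (10 classes /
#' 40 clusters, 20k cells per modality) so full pipelines run in seconds.
#'
#' @param n_cells_scrna,n_cells_spatial Number of cells in the scRNA-seq-like
#'   and spatial datasets.
#' @param taxonomy_shape Named integer vector with entries `n_class`,
#'   `n_subclass_per_class`, `n_supertype_per_subclass`,
#'   `n_cluster_per_supertype`.
#' @param genes Ordered gene-name vector (default [htr_genes()]).
#' @param panel_genes Subset of `genes` measured by the spatial dataset
#'   (default [htr_panel_genes()]).
#' @param detection_prob Optional cluster x gene matrix of Bernoulli
#'   detection probabilities in \[0,1\]. When `NULL` a probability landscape
#'   is drawn deterministically from `seed`: per-gene base prevalence
#'   log-uniform on (0.005, 0.35) — most family genes rare, a few
#'   widespread — with per-cluster effects N(0, 1.5) on the logit scale,
#'   emulating the skewed per-gene prevalence spread and strong cluster
#'   structure of real whole-brain data.
#' @param amount_mean,amount_sd Per-gene mean/sd of *detected*
#'   log-expression (recycled). Detected values are drawn from a normal
#'   truncated strictly above the detection threshold; undetected values
#'   are 0, so the planted Bernoulli structure survives thresholding
#'   exactly. The default mean rises with the gene's overall detection
#'   probability, emulating the empirical coupling between a gene's
#'   prevalence and its within-cell expression level.
#' @param spatial_amount_mean,spatial_amount_sd Same, for the spatial
#'   modality (relative to the spatial detection threshold).
#' @param neighborhood_map Named character vector class -> neighborhood.
#'   Default cycles classes over 4 neighborhood labels.
#' @param neurotransmitter_map Named character vector cluster ->
#'   neurotransmitter. Default cycles clusters over
#'   Glut/Gaba/None/Sero/Chol/Dopa (the first three dominate real data).
#' @param cluster_weights Optional sampling weights per cluster (uniform
#'   when `NULL`).
#' @param n_sections Number of brain sections along the anteroposterior
#'   (AP) axis.
#' @param section_axis_range Numeric length-2 interval of AP coordinates.
#' @param n_divisions,n_structures_per_division Grid resolution of the
#'   deterministic parcellation rule (structures nest inside divisions).
#' @param spatial_scale Multiplier in \[0,1\] applied to all spatial
#'   detection probabilities, emulating the systematic sensitivity offset
#'   between sequencing- and imaging-based modalities.
#' @param seed Integer root seed; all sub-draws derive from it.
#'
#' @return A `synthetic_config` list, validated.
#' @seealso [generate_taxonomy()], [generate_expression()],
#'   [generate_spatial()], [ground_truth()]
#' @export
#' @examples
#' cfg <- synthetic_config(n_cells_scrna = 500, n_cells_spatial = 500, seed = 7)
#' cells <- generate_taxonomy(cfg)
#' expr <- generate_expression(cells, cfg)
synthetic_config <- function(n_cells_scrna = 20000,
                             n_cells_spatial = 20000,
                             taxonomy_shape = c(n_class = 10,
                                                n_subclass_per_class = 2,
                                                n_supertype_per_subclass = 2,
                                                n_cluster_per_supertype = 1),
                             genes = htr_genes(),
                             panel_genes = htr_panel_genes(),
                             detection_prob = NULL,
                             amount_mean = NULL,
                             amount_sd = 0.8,
                             spatial_amount_mean = NULL,
                             spatial_amount_sd = 0.4,
                             neighborhood_map = NULL,
                             neurotransmitter_map = NULL,
                             cluster_weights = NULL,
                             n_sections = 10,
                             section_axis_range = c(0, 10),
                             n_divisions = 4,
                             n_structures_per_division = 3,
                             spatial_scale = 1,
                             seed = 1L) {
  shape_names <- c("n_class", "n_subclass_per_class",
                   "n_supertype_per_subclass", "n_cluster_per_supertype")
  if (!all(shape_names %in% names(taxonomy_shape))) {
    stop("taxonomy_shape must have entries ", paste(shape_names, collapse = ", "),
         call. = FALSE)
  }
  taxonomy_shape <- taxonomy_shape[shape_names]
  if (!all(vapply(taxonomy_shape, is_count, logical(1)))) {
    stop("taxonomy_shape entries must be positive integers", call. = FALSE)
  }
  if (!is_count(n_cells_scrna) || !is_count(n_cells_spatial)) {
    stop("cell counts must be positive integers", call. = FALSE)
  }
  if (!all(panel_genes %in% genes)) {
    stop("panel_genes must be a subset of genes", call. = FALSE)
  }
  if (length(panel_genes) < 1) stop("panel_genes must be non-empty", call. = FALSE)
  if (!is_count(n_sections)) stop("n_sections must be a positive integer", call. = FALSE)
  if (length(section_axis_range) != 2 || diff(section_axis_range) <= 0) {
    stop("section_axis_range must be an increasing numeric interval", call. = FALSE)
  }
  if (spatial_scale < 0 || spatial_scale > 1) {
    stop("spatial_scale must lie in [0, 1]", call. = FALSE)
  }

  n_cluster <- prod(taxonomy_shape)
  tax <- build_taxonomy_table(taxonomy_shape)

  if (is.null(detection_prob)) {
    detection_prob <- withr::with_seed(derive_seed(seed, 101), {
      base <- exp(runif(length(genes), log(0.005), log(0.35)))
      eff <- matrix(rnorm(n_cluster * length(genes), 0, 1.5),
                    nrow = n_cluster)
      stats::plogis(sweep(eff, 2, stats::qlogis(base), "+"))
    })
  }
  detection_prob <- as.matrix(detection_prob)
  if (nrow(detection_prob) != n_cluster || ncol(detection_prob) != length(genes)) {
    stop(sprintf("detection_prob must be %d clusters x %d genes",
                 n_cluster, length(genes)), call. = FALSE)
  }
  if (any(detection_prob < 0 | detection_prob > 1)) {
    stop("detection probabilities must lie in [0, 1]", call. = FALSE)
  }
  dimnames(detection_prob) <- list(tax$cluster, genes)

  if (is.null(neighborhood_map)) {
    classes <- unique(tax$class)
    neighborhood_map <- setNames(
      paste0("NB", ((seq_along(classes) - 1) %% 4) + 1), classes)
  }
  if (is.null(neurotransmitter_map)) {
    nts <- c("Glut", "Gaba", "None", "Sero", "Chol", "Dopa")
    neurotransmitter_map <- setNames(
      nts[((seq_len(n_cluster) - 1) %% length(nts)) + 1], tax$cluster)
  }
  if (!all(tax$class %in% names(neighborhood_map))) {
    stop("neighborhood_map must cover every class", call. = FALSE)
  }
  if (!all(tax$cluster %in% names(neurotransmitter_map))) {
    stop("neurotransmitter_map must cover every cluster", call. = FALSE)
  }
  if (!is.null(cluster_weights) && length(cluster_weights) != n_cluster) {
    stop("cluster_weights must have one weight per cluster", call. = FALSE)
  }

  structure(
    list(
      n_cells_scrna = as.integer(n_cells_scrna),
      n_cells_spatial = as.integer(n_cells_spatial),
      taxonomy_shape = taxonomy_shape,
      taxonomy = tax,
      genes = genes,
      panel_genes = panel_genes,
      detection_prob = detection_prob,
      amount_mean = amount_mean,
      amount_sd = amount_sd,
      spatial_amount_mean = spatial_amount_mean,
      spatial_amount_sd = spatial_amount_sd,
      neighborhood_map = neighborhood_map,
      neurotransmitter_map = neurotransmitter_map,
      cluster_weights = cluster_weights,
      n_sections = as.integer(n_sections),
      section_axis_range = as.numeric(section_axis_range),
      n_divisions = as.integer(n_divisions),
      n_structures_per_division = as.integer(n_structures_per_division),
      spatial_scale = spatial_scale,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Deterministic cluster -> (supertype, subclass, class) naming; one row per
# cluster. Nesting is by integer division, so every cluster has exactly one
# parent at each level.
build_taxonomy_table <- function(shape) {
  n_class <- shape[["n_class"]]
  n_sub <- n_class * shape[["n_subclass_per_class"]]
  n_sup <- n_sub * shape[["n_supertype_per_subclass"]]
  n_clu <- n_sup * shape[["n_cluster_per_supertype"]]
  clu <- seq_len(n_clu) - 1L
  sup <- clu %/% shape[["n_cluster_per_supertype"]]
  sub <- sup %/% shape[["n_supertype_per_subclass"]]
  cla <- sub %/% shape[["n_subclass_per_class"]]
  tibble::tibble(
    cluster = sprintf("cl%04d", clu + 1L),
    supertype = sprintf("T%03d", sup + 1L),
    subclass = sprintf("S%03d", sub + 1L),
    class = sprintf("C%02d", cla + 1L)
  )
}

#' Generate a synthetic cell-metadata table
#'
#' Draws `n_cells_scrna` cells, assigns each a cluster (uniformly unless
#' `cluster_weights` is set), derives the three upper taxonomy levels
#' deterministically from the cluster, attaches neighborhood and
#' neurotransmitter labels via the configured maps, and emits placeholder
#' 2-D embedding coordinates. Generation is a pure function of the config
#' seed: the same config yields bit-identical tables.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per cell: `cell_label`, `class`,
#'   `subclass`, `supertype`, `cluster`, `neighborhood`,
#'   `neurotransmitter`, `embedding_x`, `embedding_y`.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cells_scrna
  tax <- config$taxonomy
  withr::with_seed(derive_seed(config$seed, 1), {
    idx <- sample.int(nrow(tax), n, replace = TRUE, prob = config$cluster_weights)
    tibble::tibble(
      cell_label = sprintf("cell_%07d", seq_len(n)),
      class = tax$class[idx],
      subclass = tax$subclass[idx],
      supertype = tax$supertype[idx],
      cluster = tax$cluster[idx],
      neighborhood = unname(config$neighborhood_map[tax$class[idx]]),
      neurotransmitter = unname(config$neurotransmitter_map[tax$cluster[idx]]),
      embedding_x = runif(n, -10, 10),
      embedding_y = runif(n, -10, 10)
    )
  })
}

# Truncated-normal draw strictly above `lower`; vectorised over mu.
rtrunc_above <- function(n, mu, sd, lower) {
  lo <- pnorm((lower - mu) / sd)
  u <- runif(n, lo, 1)
  x <- mu + sd * qnorm(u)
  # inverse-CDF can land exactly on the bound at the float edge
  pmax(x, lower + 1e-9)
}

#' Generate a synthetic expression matrix
#'
#' For each cell and gene, detection is Bernoulli with the planted
#' per-cluster probability; detected values are drawn strictly above the
#' detection threshold from a truncated normal, undetected values are 0.
#' The matrix rows are aligned to the cell table's row order.
#'
#' @param cells Cell table from [generate_taxonomy()] (same config).
#' @param config A [synthetic_config()].
#' @param thresholds A [thresholds()] object; the scRNA-seq detection
#'   threshold anchors the amount model.
#' @return Numeric matrix, cells x genes, with `cell_label` rownames.
#' @export
generate_expression <- function(cells, config, thresholds = htrmap::thresholds()) {
  stopifnot(inherits(config, "synthetic_config"))
  assert_columns(cells, c("cell_label", "cluster"), "cell table")
  if (!all(cells$cluster %in% rownames(config$detection_prob))) {
    stop("cell table clusters do not match the config taxonomy", call. = FALSE)
  }
  thr <- thresholds$detection_scrna
  # default amount model couples mean detected amount to the gene's overall
  # detection probability: widespread genes also run higher within cells
  mu <- config$amount_mean %||%
    (thr + 0.5 + 2.5 * colMeans(config$detection_prob))
  mu <- rep_len(mu, length(config$genes))
  sd <- rep_len(config$amount_sd, length(config$genes))
  idx <- match(cells$cluster, rownames(config$detection_prob))
  n <- nrow(cells)
  expr <- matrix(0, nrow = n, ncol = length(config$genes),
                 dimnames = list(cells$cell_label, config$genes))
  withr::with_seed(derive_seed(config$seed, 2), {
    for (j in seq_along(config$genes)) {
      p <- config$detection_prob[idx, j]
      det <- runif(n) < p
      k <- sum(det)
      if (k > 0) expr[det, j] <- rtrunc_above(k, mu[j], sd[j], thr)
    }
  })
  expr
}

# Deterministic grid parcellation: divisions are vertical bands of x,
# structures split each band along y. Every structure name embeds its
# division, so the structure -> division map is single-valued by
# construction.
assign_parcellation <- function(x, y, n_div, n_struct_per_div) {
  dx <- pmin(floor(x * n_div), n_div - 1) + 1
  sy <- pmin(floor(y * n_struct_per_div), n_struct_per_div - 1) + 1
  division <- sprintf("DIV%02d", dx)
  structure_lab <- sprintf("%s-ST%02d", division, sy)
  tibble::tibble(division = division, structure = structure_lab)
}

#' Generate a synthetic spatial (MERFISH-like) cell table
#'
#' Spatial cells are drawn with the same cluster-label machinery as the
#' scRNA-seq side, so cluster labels form a shared vocabulary between the
#' two modalities (emulating cross-dataset label integration). Each cell
#' gets section-plane coordinates, an anteroposterior (AP) coordinate whose
#' discretization is the section label, a (division, structure) pair from
#' the deterministic grid parcellation, and expression values for the panel
#' genes only. `spatial_scale` shrinks all detection probabilities to
#' emulate the systematic sensitivity offset between modalities.
#'
#' @param config A [synthetic_config()].
#' @param thresholds A [thresholds()] object; the spatial detection
#'   threshold anchors the spatial amount model.
#' @return A tibble with one row per spatial cell: `cell_label`, `x`, `y`,
#'   `ap_coordinate`, `section_label`, `division`, `structure`, taxonomy
#'   labels, and one numeric column per panel gene.
#' @export
generate_spatial <- function(config, thresholds = htrmap::thresholds()) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cells_spatial
  tax <- config$taxonomy
  thr <- thresholds$detection_spatial
  mu <- config$spatial_amount_mean %||% (thr + 0.7)
  mu <- rep_len(mu, length(config$panel_genes))
  sd <- rep_len(config$spatial_amount_sd, length(config$panel_genes))
  rng <- config$section_axis_range

  withr::with_seed(derive_seed(config$seed, 3), {
    idx <- sample.int(nrow(tax), n, replace = TRUE, prob = config$cluster_weights)
    x <- runif(n)
    y <- runif(n)
    ap <- runif(n, rng[1], rng[2])
    sec <- pmin(floor((ap - rng[1]) / diff(rng) * config$n_sections),
                config$n_sections - 1) + 1
    parc <- assign_parcellation(x, y, config$n_divisions,
                                config$n_structures_per_division)
    out <- tibble::tibble(
      cell_label = sprintf("spatial_%07d", seq_len(n)),
      x = x, y = y,
      ap_coordinate = ap,
      section_label = sprintf("sec%02d", sec),
      division = parc$division,
      structure = parc$structure,
      class = tax$class[idx],
      subclass = tax$subclass[idx],
      supertype = tax$supertype[idx],
      cluster = tax$cluster[idx]
    )
    for (g in config$panel_genes) {
      p <- config$detection_prob[idx, g] * config$spatial_scale
      det <- runif(n) < p
      v <- numeric(n)
      j <- match(g, config$panel_genes)
      if (any(det)) v[det] <- rtrunc_above(sum(det), mu[j], sd[j], thr)
      out[[g]] <- v
    }
    out
  })
}

#' Planted ground truth of a synthetic configuration
#'
#' Returns the quantities the generator plants, against which downstream
#' estimates can be checked: the per-cluster prevalence (percent), the
#' per-gene enriched-cluster sets at the configured enrichment fraction,
#' and per-class mean detection-probability profiles (used by decoding
#' tests).
#'
#' @param config A [synthetic_config()].
#' @param thresholds A [thresholds()] object supplying
#'   `enrichment_fraction`.
#' @return A list with `planted_prevalence` (cluster x gene percent
#'   matrix), `planted_enriched` (named list gene -> cluster character
#'   vector) and `planted_group_profiles` (class x gene probability
#'   matrix).
#' @export
ground_truth <- function(config, thresholds = htrmap::thresholds()) {
  stopifnot(inherits(config, "synthetic_config"))
  p <- config$detection_prob
  frac <- thresholds$enrichment_fraction / 100
  enriched <- lapply(config$genes, function(g) {
    rownames(p)[if (thresholds$enrichment_inclusive) p[, g] >= frac else p[, g] > frac]
  })
  names(enriched) <- config$genes
  cls <- config$taxonomy$class
  profiles <- rowsum(p, cls) / as.vector(table(cls)[sort(unique(cls))])
  list(
    planted_prevalence = 100 * p,
    planted_enriched = enriched,
    planted_group_profiles = profiles
  )
}
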