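# Detection thresholding and prevalence / amount statistics by any
# taxonomy level. Prevalence — the percentage of cells in a group whose
# expression of a gene exceeds the detection threshold — is the central
# statistic of the whole analysis.

#' Detection thresholds
#'
#' The scRNA-seq detection threshold operates on the log(CPM) scale
#' (default 3.5, the stringent cutoff used to call neurotransmitter
#' release in the reference taxonomy); the spatial threshold operates on
#' the imaging modality's expression scale (default 0.3). Comparisons are
#' strict (`>`) by default: a value exactly at the threshold is NOT
#' detected. `enrichment_fraction` (percent, default 70) is the in-cluster
#' prevalence a cluster must reach to count as enriched for a gene;
#' `enrichment_inclusive` keeps the "at least 70%" reading (`>=`) rather
#' than strict `>`.
#'
#' @param detection_scrna scRNA-seq detection threshold (log(CPM)).
#' @param detection_spatial Spatial detection threshold.
#' @param enrichment_fraction Enrichment threshold, percent in (0, 100].
#' @param strict Use strict `>` for detection (default TRUE).
#' @param enrichment_inclusive Use `>=` for enrichment (default TRUE).
#' @return A `thresholds` list.
#' @export
thresholds <- function(detection_scrna = 3.5,
                       detection_spatial = 0.3,
                       enrichment_fraction = 70,
                       strict = TRUE,
                       enrichment_inclusive = TRUE) {
  stopifnot(is.finite(detection_scrna), is.finite(detection_spatial),
            is.finite(enrichment_fraction),
            enrichment_fraction > 0, enrichment_fraction <= 100)
  structure(
    list(detection_scrna = detection_scrna,
         detection_spatial = detection_spatial,
         enrichment_fraction = enrichment_fraction,
         strict = strict,
         enrichment_inclusive = enrichment_inclusive),
    class = "htr_thresholds"
  )
}

#' Threshold an expression matrix into a boolean detection mask
#'
#' @param expr Numeric cells x genes matrix.
#' @param thresholds A [thresholds()] object.
#' @param which Which dataset kind the values come from; selects the
#'   threshold (`"scrna"` or `"spatial"`).
#' @return Logical matrix of the same shape and dimnames, with a
#'   `"provenance"` attribute recording the threshold applied.
#' @export
detect <- function(expr, thresholds = htrmap::thresholds(),
                   which = c("scrna", "spatial")) {
  which <- match.arg(which)
  cutoff <- switch(which,
    scrna = thresholds$detection_scrna,
    spatial = thresholds$detection_spatial)
  mask <- if (thresholds$strict) expr > cutoff else expr >= cutoff
  attr(mask, "provenance") <- list(which = which, cutoff = cutoff,
                                   strict = thresholds$strict)
  mask
}

# Align a mask's rows to cell metadata and return the grouping vector.
group_vector <- function(mask, cells, level) {
  if (!level %in% names(cells)) {
    stop("unknown grouping level: ", level, call. = FALSE)
  }
  idx <- match(rownames(mask), cells$cell_label)
  if (anyNA(idx)) {
    stop("mask rows missing from the cell table", call. = FALSE)
  }
  cells[[level]][idx]
}

#' Prevalence of each gene by group
#'
#' For every group at the chosen metadata level and every gene, the
#' percentage of the group's cells in which the gene is detected. Groups
#' with zero cells are omitted (the ratio is undefined), never reported
#' as 0.
#'
#' @param mask Detection mask from [detect()], rownames = cell labels.
#' @param cells Cell table containing `level`.
#' @param level Metadata column to group by (e.g. `"class"`,
#'   `"neighborhood"`, `"cluster"`).
#' @return Tidy tibble with columns `group`, `gene`, `prevalence`
#'   (percent in \[0,100\]) and `n_cells`; the grouping level is stored in
#'   the `"level"` attribute.
#' @export
prevalence_by_group <- function(mask, cells, level) {
  grp <- group_vector(mask, cells, level)
  counts <- rowsum(mask + 0, grp)
  n <- as.vector(table(grp)[rownames(counts)])
  prev <- sweep(counts, 1, n, "/") * 100
  out <- tibble::as_tibble(prev, rownames = "group")
  out <- tidyr::pivot_longer(out, -"group", names_to = "gene",
                             values_to = "prevalence")
  out$n_cells <- n[match(out$group, rownames(prev))]
  out <- out[order(out$group, match(out$gene, colnames(mask))), ]
  attr(out, "level") <- level
  out
}

#' Prevalence of detecting at least one gene of a set
#'
#' @param mask Detection mask.
#' @param gene_set Genes to consider (default: all columns).
#' @return Percent of cells detecting >= 1 gene of the set.
#' @export
prevalence_any <- function(mask, gene_set = colnames(mask)) {
  stopifnot(length(gene_set) >= 1)
  if (!all(gene_set %in% colnames(mask))) {
    stop("gene_set contains genes absent from the mask", call. = FALSE)
  }
  100 * mean(rowSums(mask[, gene_set, drop = FALSE]) > 0)
}

#' Mean expression amount by group
#'
#' Per group x gene mean of expression values, optionally restricted to
#' detected cells (the violin-plot convention: amounts of RNA actually
#' detected). Groups with no detected cells for a gene are reported as
#' missing under `detected_only = TRUE`.
#'
#' @param expr Expression matrix.
#' @param mask Detection mask (same shape), required when
#'   `detected_only = TRUE`.
#' @param cells Cell table.
#' @param level Grouping column.
#' @param detected_only Restrict to detected cells (default TRUE).
#' @return Tibble with `group`, `gene`, `mean_amount`, `n_detected`.
#' @export
mean_amount_by_group <- function(expr, mask = NULL, cells, level,
                                 detected_only = TRUE) {
  grp <- group_vector(expr, cells, level)
  if (detected_only) {
    stopifnot(!is.null(mask), all(dim(mask) == dim(expr)))
    sums <- rowsum(expr * mask, grp)
    ns <- rowsum(mask + 0, grp)
  } else {
    sums <- rowsum(expr, grp)
    ns <- rowsum(matrix(1, nrow(expr), ncol(expr), dimnames = dimnames(expr)), grp)
  }
  mean_amt <- sums / ns
  mean_amt[ns == 0] <- NA_real_
  out <- tibble::as_tibble(mean_amt, rownames = "group")
  out <- tidyr::pivot_longer(out, -"group", names_to = "gene",
                             values_to = "mean_amount")
  nlong <- tibble::as_tibble(ns, rownames = "group")
  nlong <- tidyr::pivot_longer(nlong, -"group", names_to = "gene",
                               values_to = "n_detected")
  out <- dplyr::left_join(out, nlong, by = c("group", "gene"))
  attr(out, "level") <- level
  out
}

#' Shared variance between per-gene prevalence and mean amount
#'
#' Squared Pearson correlation, across genes, between each gene's overall
#' prevalence and its mean detected expression amount. Quantifies how much
#' genes that are widespread across cells also run higher within
#' individual cells.
#'
#' @param expr Expression matrix.
#' @param mask Detection mask of the same shape.
#' @return R-squared (scalar).
#' @export
prevalence_amount_r2 <- function(expr, mask) {
  stopifnot(ncol(expr) >= 3, all(dim(mask) == dim(expr)))
  prev <- 100 * colMeans(mask)
  n_det <- colSums(mask)
  amt <- colSums(expr * mask) / n_det
  keep <- n_det > 0
  if (sum(keep) < 3) stop("need >= 3 genes with detected cells", call. = FALSE)
  cor(prev[keep], amt[keep])^2
}

#' Top groups by absolute detected-cell count for a gene
#'
#' Groups ranked by the absolute number of cells detecting `gene`
#' (descending; ties broken lexicographically by group name); the top `k`
#' are returned with their counts. This is the "top ten classes by raw
#' count" view.
#'
#' @param mask Detection mask.
#' @param cells Cell table.
#' @param gene Gene name.
#' @param level Grouping column.
#' @param k Number of groups to keep (default 10).
#' @return Tibble `group`, `count`, in rank order.
#' @export
top_groups_by_count <- function(mask, cells, gene, level, k = 10) {
  stopifnot(is_count(k))
  if (!gene %in% colnames(mask)) stop("gene absent from mask: ", gene, call. = FALSE)
  grp <- group_vector(mask, cells, level)
  counts <- rowsum(mask[, gene] + 0, grp)[, 1]
  ord <- order(-counts, names(counts))
  top <- counts[ord][seq_len(min(k, length(counts)))]
  tibble::tibble(group = names(top), count = unname(top))
}
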