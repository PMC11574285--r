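# Cross-modal spatial mapping. The spatial gene panel misses some family
# genes; the bridge is the shared cluster vocabulary: clusters enriched
# for a gene in the scRNA-seq dataset are located in space through their
# labels, which works even for off-panel genes. A direct mode (spatial
# detection only) is available when the gene is on the panel.

#' Identify clusters enriched for a gene
#'
#' A cluster is enriched when its in-cluster prevalence of `gene` reaches
#' the enrichment fraction (default: at least 70% of the cluster's cells
#' detect the gene). Also reports the enriched fraction: the percentage
#' of all gene-detecting cells that belong to retained clusters — when
#' small, the cross-reference view covers only a minority of the gene's
#' expression and the direct mode is the honest alternative.
#'
#' @param mask Detection mask (scRNA-seq side).
#' @param cells Cell table with `cluster` labels.
#' @param gene Gene name.
#' @param thresholds A [thresholds()] object.
#' @return An `enriched_clusters` list: `gene`, `clusters`,
#'   `in_cluster_prevalence` (named, retained clusters only),
#'   `enriched_fraction` (percent), `n_detecting`.
#' @export
find_enriched_clusters <- function(mask, cells, gene,
                                   thresholds = htrmap::thresholds()) {
  if (!gene %in% colnames(mask)) stop("gene absent from mask: ", gene, call. = FALSE)
  prev <- prevalence_by_group(mask[, gene, drop = FALSE], cells, "cluster")
  cut <- thresholds$enrichment_fraction
  keep <- if (thresholds$enrichment_inclusive) {
    prev$prevalence >= cut
  } else {
    prev$prevalence > cut
  }
  retained <- prev[keep, , drop = FALSE]
  det <- mask[, gene]
  grp <- group_vector(mask, cells, "cluster")
  n_det <- sum(det)
  frac <- if (n_det == 0) 0 else 100 * sum(det & grp %in% retained$group) / n_det
  structure(
    list(gene = gene,
         clusters = retained$group,
         in_cluster_prevalence = setNames(retained$prevalence, retained$group),
         enriched_fraction = frac,
         n_detecting = n_det),
    class = "enriched_clusters"
  )
}

#' Project enriched clusters into the spatial dataset
#'
#' Returns the spatial cells whose cluster label belongs to the enriched
#' set. Works whether or not the gene is on the spatial panel — that is
#' the point of the method.
#'
#' @param enriched An [find_enriched_clusters()] result.
#' @param spatial Spatial cell table.
#' @return Subset of `spatial` (possibly empty).
#' @export
cross_reference <- function(enriched, spatial) {
  stopifnot(inherits(enriched, "enriched_clusters"))
  assert_columns(spatial, "cluster", "spatial cell table")
  spatial[spatial$cluster %in% enriched$clusters, , drop = FALSE]
}

# Per-cell indicator used by the regional / AP statistics.
spatial_flag <- function(spatial, mode, enriched = NULL, gene = NULL,
                         thresholds = htrmap::thresholds()) {
  if (mode == "crossref") {
    stopifnot(inherits(enriched, "enriched_clusters"))
    spatial$cluster %in% enriched$clusters
  } else {
    if (is.null(gene) || !gene %in% names(spatial)) {
      stop("direct mode needs a gene present on the spatial panel", call. = FALSE)
    }
    if (thresholds$strict) {
      spatial[[gene]] > thresholds$detection_spatial
    } else {
      spatial[[gene]] >= thresholds$detection_spatial
    }
  }
}

#' Regional prevalence across parcellation levels
#'
#' Percentage of each region's cells counted by the selected mode:
#' `"crossref"` counts cells of scRNA-seq-defined enriched clusters;
#' `"direct"` counts cells whose spatial expression of `gene` passes the
#' spatial detection threshold. Both are normalized by the total number
#' of cells in the region and ranked descending (ties broken by region
#' name).
#'
#' @param spatial Spatial cell table.
#' @param level `"division"` or `"structure"`.
#' @param mode `"crossref"` (default) or `"direct"`.
#' @param enriched Required for crossref mode.
#' @param gene Required for direct mode (must be on the panel).
#' @param thresholds A [thresholds()] object.
#' @param top_k Optional: keep only the top-k regions.
#' @return Tibble `region`, `prevalence`, `n_cells` (and `division` when
#'   ranking structures), ranked.
#' @export
prevalence_by_parcellation <- function(spatial,
                                       level = c("division", "structure"),
                                       mode = c("crossref", "direct"),
                                       enriched = NULL, gene = NULL,
                                       thresholds = htrmap::thresholds(),
                                       top_k = NULL) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  assert_columns(spatial, level, "spatial cell table")
  flag <- spatial_flag(spatial, mode, enriched, gene, thresholds)
  grp <- spatial[[level]]
  counts <- rowsum(flag + 0, grp)[, 1]
  n <- as.vector(table(grp)[names(counts)])
  out <- tibble::tibble(region = names(counts),
                        prevalence = unname(100 * counts / n),
                        n_cells = n)
  if (level == "structure") {
    map <- unique(spatial[, c("structure", "division")])
    out$division <- map$division[match(out$region, map$structure)]
  }
  out <- out[order(-out$prevalence, out$region), ]
  if (!is.null(top_k)) out <- head(out, top_k)
  out
}

#' Cross-dataset concordance of per-class prevalence
#'
#' Ordinary least-squares regression of spatial on scRNA-seq prevalence
#' over shared (group, gene) pairs. A slope below 1 quantifies the
#' systematic sensitivity offset between the imaging and sequencing
#' modalities; R-squared measures how much variability the two datasets
#' share.
#'
#' @param prev_scrna,prev_spatial [prevalence_by_group()] tibbles from
#'   the two modalities (same grouping level).
#' @param gene Optional: restrict to one gene (the per-receptor view).
#' @return List `slope`, `intercept`, `r_squared`, `n_points`.
#' @export
class_concordance <- function(prev_scrna, prev_spatial, gene = NULL) {
  a <- prev_scrna[, c("group", "gene", "prevalence")]
  b <- prev_spatial[, c("group", "gene", "prevalence")]
  if (!is.null(gene)) {
    a <- a[a$gene == gene, ]
    b <- b[b$gene == gene, ]
  }
  joined <- dplyr::inner_join(a, b, by = c("group", "gene"),
                              suffix = c("_scrna", "_spatial"))
  if (nrow(joined) < 3) stop("need >= 3 shared (group, gene) points", call. = FALSE)
  fit <- lm(prevalence_spatial ~ prevalence_scrna, data = joined)
  # summary() warns on exactly collinear inputs ("essentially perfect fit");
  # those are legitimate here (identical tables)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = r2,
       n_points = nrow(joined))
}

#' Prevalence profile along the anteroposterior axis
#'
#' Per brain section (ordered by AP coordinate): the percentage of the
#' section's cells counted by the selected mode, and — when `gene` is on
#' the spatial panel — the mean expression amount among counted cells
#' that pass the spatial detection threshold. Sections with zero cells
#' are omitted.
#'
#' @inheritParams prevalence_by_parcellation
#' @param gene Optional panel gene for the amount profile (required in
#'   direct mode).
#' @return Tibble `section_label`, `ap` (mean AP coordinate),
#'   `prevalence`, `n_cells`, `mean_amount` (NA off-panel / no counted
#'   detected cells), ordered along the axis.
#' @export
ap_profile <- function(spatial, mode = c("crossref", "direct"),
                       enriched = NULL, gene = NULL,
                       thresholds = htrmap::thresholds()) {
  mode <- match.arg(mode)
  assert_columns(spatial, c("section_label", "ap_coordinate"),
                 "spatial cell table")
  flag <- spatial_flag(spatial, mode, enriched, gene, thresholds)
  grp <- spatial$section_label
  counts <- rowsum(flag + 0, grp)[, 1]
  n <- as.vector(table(grp)[names(counts)])
  ap <- rowsum(spatial$ap_coordinate, grp)[, 1] / n
  amt <- rep(NA_real_, length(counts))
  if (!is.null(gene) && gene %in% names(spatial)) {
    det <- if (thresholds$strict) {
      spatial[[gene]] > thresholds$detection_spatial
    } else {
      spatial[[gene]] >= thresholds$detection_spatial
    }
    use <- flag & det
    s <- rowsum(spatial[[gene]] * use, grp)[, 1]
    kn <- rowsum(use + 0, grp)[, 1]
    amt <- ifelse(kn > 0, s / kn, NA_real_)
  }
  out <- tibble::tibble(section_label = names(counts),
                        ap = unname(ap),
                        prevalence = unname(100 * counts / n),
                        n_cells = n,
                        mean_amount = unname(amt))
  out[order(out$ap), ]
}

#' Select the top peak sections of an AP profile
#'
#' Local maxima of the prevalence profile (a section at least as high as
#' both neighbors; endpoints compared to their single neighbor), ranked
#' by prevalence and greedily retained subject to a minimum pairwise AP
#' spacing; the top `k` are returned. If fewer than `k` spaced peaks
#' exist, the highest remaining sections (still respecting spacing) fill
#' the list and the result is flagged via the `"filled"` attribute.
#'
#' @param profile An [ap_profile()] tibble (non-empty).
#' @param k Number of sections (default 4).
#' @param min_spacing Minimum AP distance between selected sections;
#'   default 10% of the profile's AP range.
#' @return Character vector of section labels (length <= k) in rank
#'   order, with attributes `"ap"` and `"filled"`.
#' @export
select_top_sections <- function(profile, k = 4, min_spacing = NULL) {
  stopifnot(nrow(profile) >= 1, is_count(k))
  ap <- profile$ap
  p <- profile$prevalence
  n <- length(p)
  if (is.null(min_spacing)) min_spacing <- 0.1 * diff(range(ap))
  is_peak <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || p[i] >= p[i - 1]
    right_ok <- i == n || p[i] >= p[i + 1]
    left_ok && right_ok
  }, logical(1))

  greedy <- function(cand, chosen_ap) {
    picked <- integer(0)
    for (i in cand) {
      if (all(abs(ap[i] - chosen_ap) >= min_spacing)) {
        picked <- c(picked, i)
        chosen_ap <- c(chosen_ap, ap[i])
        if (length(chosen_ap) >= k) break
      }
    }
    picked
  }

  peak_order <- which(is_peak)[order(-p[is_peak], ap[is_peak])]
  sel <- greedy(peak_order, numeric(0))
  filled <- FALSE
  if (length(sel) < k) {
    rest <- setdiff(order(-p, ap), sel)
    extra <- greedy(rest, ap[sel])
    if (length(extra) > 0) {
      sel <- c(sel, extra[seq_len(min(length(extra), k - length(sel)))])
      filled <- TRUE
    }
  }
  out <- profile$section_label[sel]
  attr(out, "ap") <- ap[sel]
  attr(out, "filled") <- filled
  out
}
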