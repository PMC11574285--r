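# Pairwise co-localization (co-transcription in the same cell),
# co-transcription count distributions, and correlation of continuous
# expression. Co-localization percentages are computed on the boolean
# detection mask; correlations on the continuous values — two different
# questions about the same cells.

#' Pairwise co-localization matrix
#'
#' Entry `[y, x]` is the percentage of cells detecting the conditioning
#' gene `y` that also detect gene `x`:
#' `100 * |cells detecting both| / |cells detecting y|`. The statistic is
#' asymmetric by construction; the diagonal is 100 for every gene with at
#' least one detecting cell. Rows whose conditioning gene is detected in
#' zero cells are reported as missing (`NA`), not 0.
#'
#' @param mask Detection mask (cells x genes logical matrix), >= 2 genes.
#' @return Genes x genes percent matrix (rows = conditioning gene) with an
#'   `"n_conditioning"` attribute of per-gene detecting-cell counts.
#' @export
coloc_matrix <- function(mask) {
  stopifnot(ncol(mask) >= 2)
  joint <- crossprod(mask + 0)            # gene x gene joint detection counts
  n_y <- diag(joint)
  out <- 100 * sweep(joint, 1, n_y, "/")
  out[n_y == 0, ] <- NA_real_
  attr(out, "n_conditioning") <- n_y
  out
}

#' Distribution of the number of genes detected per cell
#'
#' How many family genes does each cell transcribe? Reported on two
#' explicitly labeled bases: percent of all cells (including k = 0) and
#' percent of transcribing cells (k >= 1 only; `NA` at k = 0 on this
#' basis). Each basis sums to 100.
#'
#' @param mask Detection mask.
#' @return Tibble `n_genes` (0..ncol), `pct_all_cells`,
#'   `pct_positive_cells`.
#' @export
n_receptors_distribution <- function(mask) {
  k <- rowSums(mask)
  lev <- 0:ncol(mask)
  tab <- table(factor(k, levels = lev))
  n <- length(k)
  n_pos <- sum(k >= 1)
  pct_all <- 100 * as.vector(tab) / n
  pct_pos <- c(NA_real_, 100 * as.vector(tab)[-1] / n_pos)
  tibble::tibble(n_genes = lev, pct_all_cells = pct_all,
                 pct_positive_cells = pct_pos)
}

#' Percent of a gene's cells that also detect k other family genes
#'
#' Among cells detecting `gene`, the percentage that also detect at least
#' `k` *other* genes of the family.
#'
#' @param mask Detection mask.
#' @param gene Conditioning gene.
#' @param k Minimum number of other genes (>= 1).
#' @return Percent (scalar); `NA` if no cell detects `gene`.
#' @export
at_least_k_other <- function(mask, gene, k = 1) {
  stopifnot(is_count(k))
  if (!gene %in% colnames(mask)) stop("gene absent from mask: ", gene, call. = FALSE)
  sel <- mask[, gene]
  if (!any(sel)) return(NA_real_)
  others <- rowSums(mask[sel, setdiff(colnames(mask), gene), drop = FALSE])
  100 * mean(others >= k)
}

#' Gene-gene Pearson correlation of continuous expression
#'
#' Correlation of the continuous (not thresholded) expression values
#' across cells, per gene pair, optionally restricted to a metadata
#' subset (e.g. one neighborhood). Genes with zero variance in the
#' selection yield `NA` rows/columns (correlation undefined).
#'
#' @param expr Expression matrix.
#' @param cells Optional cell table for subsetting.
#' @param level,group Optional: restrict to cells whose `level` column
#'   equals `group`.
#' @return Symmetric gene x gene correlation matrix.
#' @export
correlation_matrix <- function(expr, cells = NULL, level = NULL, group = NULL) {
  if (!is.null(level)) {
    stopifnot(!is.null(cells), !is.null(group))
    keep <- cells$cell_label[cells[[level]] %in% group]
    expr <- expr[rownames(expr) %in% keep, , drop = FALSE]
  }
  if (nrow(expr) < 2) stop("need >= 2 cells after filtering", call. = FALSE)
  suppressWarnings(cor(expr))
}

#' Correlation between group prevalence profiles
#'
#' Pearson r between the per-gene prevalence profiles of each pair of
#' groups, plus per-group summaries: the mean r of each group against all
#' other groups with its standard error of the mean (the +/- convention),
#' and the overall mean over unordered pairs. Groups with near-identical
#' profiles score high; groups with distinctive receptor repertoires
#' (e.g. serotonergic or cholinergic neurons in real data) stand out with
#' low means.
#'
#' @param prev A [prevalence_by_group()] tibble with >= 2 groups.
#' @return List: `r` (group x group matrix), `per_group` (tibble `group`,
#'   `mean_r`, `sem_r`), `overall` (list `mean_r`, `sem_r` over unordered
#'   pairs).
#' @export
group_profile_correlation <- function(prev) {
  wide <- tidyr::pivot_wider(prev[, c("group", "gene", "prevalence")],
                             names_from = "gene", values_from = "prevalence")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$group
  if (nrow(m) < 2) stop("need >= 2 groups", call. = FALSE)
  r <- suppressWarnings(cor(t(m)))
  off <- r
  diag(off) <- NA
  per_group <- tibble::tibble(
    group = rownames(r),
    mean_r = unname(rowMeans(off, na.rm = TRUE)),
    sem_r = unname(apply(off, 1, function(z) {
      z <- z[!is.na(z)]
      stats::sd(z) / sqrt(length(z))
    }))
  )
  pairs <- r[upper.tri(r)]
  pairs <- pairs[!is.na(pairs)]
  list(
    r = r,
    per_group = per_group,
    overall = list(mean_r = mean(pairs),
                   sem_r = stats::sd(pairs) / sqrt(length(pairs)))
  )
}
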