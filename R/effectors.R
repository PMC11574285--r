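# Aggregate receptor expression into effector families and assign each
# cell the primary 5-HT pathway: the family with the largest summed raw
# expression. Sums use raw (unthresholded) values — the question is which
# downstream effector dominates, not whether individual genes pass
# detection.

#' Per-cell summed expression by receptor family
#'
#' @param expr Expression matrix whose genes are covered by the family
#'   map; families must be disjoint and jointly cover the matrix genes.
#' @param fmap Family map, see [htr_family_map()].
#' @return Cells x families numeric matrix.
#' @export
family_sums <- function(expr, fmap = htr_family_map()) {
  all_genes <- unlist(fmap, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("family map genes must be disjoint", call. = FALSE)
  if (!setequal(all_genes, colnames(expr))) {
    stop("family map must cover exactly the matrix genes", call. = FALSE)
  }
  out <- vapply(fmap, function(genes) {
    rowSums(expr[, genes, drop = FALSE])
  }, numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  out
}

#' Primary effector family per cell
#'
#' Argmax family per cell. Cells with all-zero sums are labeled
#' `"unassigned"`; exact ties are broken by the fixed family order of the
#' sums' columns (Htr1/5, Htr2, Htr4/6/7, Htr3 for the default map) and
#' the tie count is logged. Scaling a cell's expression by any positive
#' constant leaves its assignment unchanged.
#'
#' @param fs Cells x families matrix from [family_sums()].
#' @return Named factor (levels = families + `"unassigned"`), one label
#'   per cell.
#' @export
primary_family <- function(fs) {
  fams <- colnames(fs)
  top <- max.col(fs, ties.method = "first")
  maxval <- fs[cbind(seq_len(nrow(fs)), top)]
  lab <- fams[top]
  lab[maxval == 0] <- "unassigned"
  n_tie <- sum(rowSums(fs == maxval) > 1 & maxval > 0)
  if (n_tie > 0) {
    message(sprintf("%d exact ties broken by fixed family order", n_tie))
  }
  setNames(factor(lab, levels = c(fams, "unassigned")), rownames(fs))
}

#' Effector-family composition per group
#'
#' Per group at the chosen taxonomy level, counts and fractions of cells
#' by primary family (including `"unassigned"`). Counts are also reported
#' in thousands (the pie-chart annotation convention); fractions sum to 1
#' within each group.
#'
#' @param primary Factor from [primary_family()], named by cell label.
#' @param cells Cell table.
#' @param level Grouping column.
#' @return Tibble `group`, `family`, `count`, `count_thousands`,
#'   `fraction`.
#' @export
family_composition <- function(primary, cells, level) {
  if (!level %in% names(cells)) stop("unknown grouping level: ", level, call. = FALSE)
  idx <- match(names(primary), cells$cell_label)
  if (anyNA(idx)) stop("primary labels missing from the cell table", call. = FALSE)
  grp <- cells[[level]][idx]
  tab <- table(group = grp, family = primary)
  out <- tibble::as_tibble(as.data.frame(tab, stringsAsFactors = FALSE))
  names(out) <- c("group", "family", "count")
  totals <- rowSums(tab)
  out$count_thousands <- out$count / 1000
  out$fraction <- out$count / as.vector(totals[out$group])
  out[order(out$group, match(out$family, colnames(tab))), ]
}
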