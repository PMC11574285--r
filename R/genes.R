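#' The 14 mouse serotonin receptor genes
#'
#' The full Htr gene family in mouse: 14 subtypes across seven receptor
#' families (Htr1, Htr2, Htr3, Htr4, Htr5, Htr6, Htr7). This is the default
#' gene list throughout the package; any ordered character vector of gene
#' names can be substituted to profile a different family.
#'
#' @return Ordered character vector of 14 gene symbols.
#' @export
#' @examples
#' htr_genes()
htr_genes <- function() {
  c("Htr1a", "Htr1b", "Htr1d", "Htr1f",
    "Htr2a", "Htr2b", "Htr2c",
    "Htr3a", "Htr3b",
    "Htr4", "Htr5a", "Htr5b", "Htr6", "Htr7")
}

#' Default spatial (MERFISH-like) gene panel
#'
#' Imaging-based spatial datasets measure a fixed gene panel; the reference
#' panel covers 9 of the 14 Htr genes. Htr2b, Htr3b, Htr5a, Htr5b and Htr6
#' are absent, which is exactly why enriched-cluster cross-referencing
#' exists: it imputes spatial distributions for off-panel genes through
#' shared cluster labels.
#'
#' @return Character vector of 9 gene symbols, a subset of [htr_genes()].
#' @export
htr_panel_genes <- function() {
  setdiff(htr_genes(), c("Htr2b", "Htr3b", "Htr5a", "Htr5b", "Htr6"))
}

#' Receptor-family (primary effector) map
#'
#' Groups the 14 Htr genes into four families by shared intracellular
#' effector: Htr1/5 (Gi-coupled, cAMP decrease), Htr2 (Gq-coupled, Ca2+
#' increase), Htr4/6/7 (Gs-coupled, cAMP increase) and Htr3 (the only
#' ionotropic family). Families are disjoint and cover the full gene list.
#'
#' @return Named list mapping family label to a character vector of genes.
#' @export
#' @examples
#' htr_family_map()
htr_family_map <- function() {
  list(
    "Htr1/5"   = c("Htr1a", "Htr1b", "Htr1d", "Htr1f", "Htr5a", "Htr5b"),
    "Htr2"     = c("Htr2a", "Htr2b", "Htr2c"),
    "Htr4/6/7" = c("Htr4", "Htr6", "Htr7"),
    "Htr3"     = c("Htr3a", "Htr3b")
  )
}
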