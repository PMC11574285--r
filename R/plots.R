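# ggplot2 helpers mirroring the standard panels: prevalence heatmap,
# co-localization / confusion / attribution matrices, effector
# composition, AP profile.

#' Prevalence heatmap
#'
#' @param prev A [prevalence_by_group()] tibble.
#' @param sort_by Optional gene name: order groups by its prevalence.
#' @return A ggplot object.
#' @export
plot_prevalence_heatmap <- function(prev, sort_by = NULL) {
  if (!is.null(sort_by)) {
    ord <- prev[prev$gene == sort_by, ]
    prev$group <- factor(prev$group, levels = ord$group[order(ord$prevalence)])
  }
  ggplot2::ggplot(prev, ggplot2::aes(x = .data$gene, y = .data$group,
                                     fill = .data$prevalence)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Prevalence (%)", limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = attr(prev, "level") %||% "group") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Square matrix heatmap (co-localization / confusion / attribution)
#'
#' @param mat Labeled numeric matrix.
#' @param value_name Legend title.
#' @return A ggplot object.
#' @export
plot_matrix <- function(mat, value_name = "value") {
  df <- tibble::as_tibble(mat, rownames = "row")
  df <- tidyr::pivot_longer(df, -"row", names_to = "col", values_to = "value")
  df$row <- factor(df$row, levels = rev(rownames(mat)))
  df$col <- factor(df$col, levels = colnames(mat))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Effector-family composition bars
#'
#' @param comp A [family_composition()] tibble.
#' @return A ggplot object.
#' @export
plot_family_composition <- function(comp) {
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$group, y = .data$fraction,
                                     fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                name = "Cells (%)") +
    ggplot2::labs(x = NULL, fill = "Primary family") +
    ggplot2::theme_minimal(base_size = 9)
}

#' Anteroposterior prevalence profile
#'
#' @param profile An [ap_profile()] tibble.
#' @param top_sections Optional [select_top_sections()] result to mark.
#' @return A ggplot object.
#' @export
plot_ap_profile <- function(profile, top_sections = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$ap,
                                             y = .data$prevalence)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "Anteroposterior coordinate", y = "Prevalence (%)") +
    ggplot2::theme_minimal(base_size = 9)
  if (!is.null(top_sections)) {
    marks <- profile[profile$section_label %in% top_sections, ]
    p <- p + ggplot2::geom_point(data = marks, color = "red", size = 2)
  }
  p
}
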