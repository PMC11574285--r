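# Readers/writers for the three table kinds plus the joins that assemble
# the working dataframes. Supported containers: CSV (RFC 4180, UTF-8,
# header row) and Parquet. Matrices travel as wide tables with a
# `cell_label` first column.

cell_table_required <- c("cell_label", "class", "subclass", "supertype", "cluster")
spatial_table_required <- c("cell_label", "x", "y", "ap_coordinate",
                            "section_label", "division", "structure", "cluster")

guess_format <- function(path, format = c("auto", "csv", "parquet")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("parquet", "pq")) "parquet" else "csv"
}

read_table_file <- function(path, format) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(guess_format(path, format),
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    parquet = tibble::as_tibble(arrow::read_parquet(path))
  )
}

write_table_file <- function(df, path, format) {
  switch(guess_format(path, format),
    csv = readr::write_csv(df, path),
    parquet = arrow::write_parquet(df, path)
  )
  invisible(path)
}

validate_cell_table <- function(df) {
  assert_columns(df, cell_table_required, "cell table")
  if (anyDuplicated(df$cell_label)) {
    stop("cell_label values must be unique", call. = FALSE)
  }
  tax <- df[, c("class", "subclass", "supertype", "cluster")]
  if (anyNA(tax)) {
    stop("taxonomy labels (class/subclass/supertype/cluster) must be non-null",
         call. = FALSE)
  }
  df
}

#' Read / write a cell-metadata table
#'
#' One row per cell with the unique `cell_label` key, the four nested
#' taxonomy labels, and any further metadata columns (neighborhood,
#' neurotransmitter, embedding coordinates, ...), all preserved. A missing
#' required column raises a schema error naming it; duplicate cell labels
#' or null taxonomy labels are rejected.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"` (default, by extension), `"csv"` or `"parquet"`.
#' @return A validated tibble.
#' @export
read_cell_table <- function(path, format = c("auto", "csv", "parquet")) {
  validate_cell_table(read_table_file(path, match.arg(format)))
}

#' @rdname read_cell_table
#' @param cells A cell table.
#' @export
write_cell_table <- function(cells, path, format = c("auto", "csv", "parquet")) {
  write_table_file(validate_cell_table(cells), path, match.arg(format))
}

#' Read / write an expression matrix
#'
#' The on-disk layout is a wide table whose first column is `cell_label`
#' and remaining columns are genes, values on the log(CPM) scale (>= 0).
#' Missing values are treated as 0 (undetected) with a logged count, so
#' threshold semantics are unaffected and NAs never propagate.
#'
#' @inheritParams read_cell_table
#' @return Numeric matrix, cells x genes, rownames = `cell_label`.
#' @export
read_expression_matrix <- function(path, format = c("auto", "csv", "parquet")) {
  df <- read_table_file(path, match.arg(format))
  assert_columns(df, "cell_label", "expression matrix")
  if (anyDuplicated(df$cell_label)) {
    stop("cell_label values must be unique", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "cell_label"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$cell_label
  n_na <- sum(is.na(m))
  if (n_na > 0) {
    message(sprintf("%d missing expression values treated as 0 (undetected)", n_na))
    m[is.na(m)] <- 0
  }
  if (any(m < 0)) stop("expression values must be non-negative", call. = FALSE)
  m
}

#' @rdname read_expression_matrix
#' @param expr Numeric cells x genes matrix with `cell_label` rownames.
#' @export
write_expression_matrix <- function(expr, path, format = c("auto", "csv", "parquet")) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  df <- tibble::as_tibble(expr)
  df <- dplyr::bind_cols(tibble::tibble(cell_label = rownames(expr)), df)
  write_table_file(df, path, match.arg(format))
}

validate_spatial_table <- function(df) {
  assert_columns(df, spatial_table_required, "spatial cell table")
  if (anyDuplicated(df$cell_label)) {
    stop("cell_label values must be unique", call. = FALSE)
  }
  map <- unique(df[, c("structure", "division")])
  if (anyDuplicated(map$structure)) {
    stop("every structure must map to exactly one division", call. = FALSE)
  }
  df
}

#' Read / write a spatial cell table
#'
#' One row per spatial cell: coordinates, AP coordinate and section label,
#' the nested (division, structure) parcellation pair, the taxonomy labels
#' transferred by cross-dataset label integration, and one column per
#' panel gene. Validation enforces unique cell labels and a single-valued
#' structure -> division map.
#'
#' @inheritParams read_cell_table
#' @return A validated tibble.
#' @export
read_spatial_table <- function(path, format = c("auto", "csv", "parquet")) {
  validate_spatial_table(read_table_file(path, match.arg(format)))
}

#' @rdname read_spatial_table
#' @param spatial A spatial cell table.
#' @export
write_spatial_table <- function(spatial, path, format = c("auto", "csv", "parquet")) {
  write_table_file(validate_spatial_table(spatial), path, match.arg(format))
}

#' Join cell metadata to an expression matrix
#'
#' Inner join on `cell_label`. The expression matrix's row order is
#' preserved; cells lacking expression rows (and expression rows lacking
#' metadata) are dropped with a logged count. Zero key overlap is an
#' error.
#'
#' @param cells Cell table.
#' @param expr Expression matrix with `cell_label` rownames.
#' @return A tibble: metadata columns followed by one column per gene.
#' @export
join_expression <- function(cells, expr) {
  validate_cell_table(cells)
  stopifnot(is.matrix(expr))
  keys <- rownames(expr) %||% character(0)
  keep <- keys[keys %in% cells$cell_label]
  if (length(keep) == 0) {
    stop("no overlap between cell table and expression matrix keys", call. = FALSE)
  }
  n_drop_cells <- sum(!cells$cell_label %in% keep)
  n_drop_expr <- nrow(expr) - length(keep)
  if (n_drop_cells > 0 || n_drop_expr > 0) {
    message(sprintf(
      "join dropped %d cells without expression and %d expression rows without metadata",
      n_drop_cells, n_drop_expr))
  }
  meta <- cells[match(keep, cells$cell_label), , drop = FALSE]
  dplyr::bind_cols(meta, tibble::as_tibble(expr[keep, , drop = FALSE]))
}

#' Expand multi-neighborhood memberships
#'
#' Some cells belong to several neighborhoods; neighborhood-grouped
#' statistics must count them once per membership. This returns a
#' separate, possibly row-duplicated table to be used *only* for
#' neighborhood-grouped computations; the unduplicated input remains the
#' source for every other grouping. Cells absent from the membership table
#' keep their single neighborhood label.
#'
#' @param cells Cell table with a `neighborhood` column.
#' @param membership Tibble with columns `cell_label`, `neighborhood`
#'   (one row per membership).
#' @return Cell table with one row per (cell, neighborhood) pair.
#' @export
expand_memberships <- function(cells, membership) {
  assert_columns(cells, c("cell_label", "neighborhood"), "cell table")
  assert_columns(membership, c("cell_label", "neighborhood"), "membership table")
  in_m <- cells$cell_label %in% membership$cell_label
  expanded <- dplyr::inner_join(
    dplyr::select(cells[in_m, , drop = FALSE], -"neighborhood"),
    membership, by = "cell_label")
  out <- dplyr::bind_rows(cells[!in_m, , drop = FALSE], expanded)
  out[order(match(out$cell_label, cells$cell_label)), , drop = FALSE]
}

#' Write / read the ground-truth sidecar
#'
#' Serializes the planted quantities of a synthetic configuration (see
#' [ground_truth()]) to JSON next to the generated tables so recovery
#' tests never need the config object itself.
#'
#' @param truth A [ground_truth()] list.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(truth, path) {
  pack <- function(m) {
    list(rows = rownames(m), cols = colnames(m), values = unname(m))
  }
  out <- list(
    planted_prevalence = pack(truth$planted_prevalence),
    planted_enriched = truth$planted_enriched,
    planted_group_profiles = pack(truth$planted_group_profiles)
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(x) {
    m <- as.matrix(x$values)
    dimnames(m) <- list(x$rows, x$cols)
    m
  }
  list(
    planted_prevalence = unpack(raw$planted_prevalence),
    planted_enriched = lapply(raw$planted_enriched, as.character),
    planted_group_profiles = unpack(raw$planted_group_profiles)
  )
}
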