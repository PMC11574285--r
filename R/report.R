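# Static single-page HTML report standing in for the interactive
# dashboards: every figure is rendered from (and corresponds 1:1 to) a
# serialized table in the results directory, embedded base64 so the page
# is self-contained. Missing results render as explicit stubs rather than
# errors.

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 25) {
  df <- head(df, max_rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 4, format = "fg"))
  header <- paste0("<tr>", paste0("<th>", html_escape(names(df)), "</th>",
                                  collapse = ""), "</tr>")
  rows <- apply(df, 1, function(r) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(r)), "</td>",
                          collapse = ""), "</tr>")
  })
  paste0("<table>", header, paste(rows, collapse = ""), "</table>")
}

embed_plot <- function(p, width = 6, height = 4) {
  tmp <- tempfile(fileext = ".png")
  on.exit(unlink(tmp), add = TRUE)
  ggplot2::ggsave(tmp, p, width = width, height = height, dpi = 96,
                  device = grDevices::png)
  raw <- readBin(tmp, "raw", file.info(tmp)$size)
  sprintf('<img src="data:image/png;base64,%s" />', jsonlite::base64_enc(raw))
}

report_section <- function(title, body) {
  sprintf("<section><h2>%s</h2>%s</section>", html_escape(title), body)
}

stub <- "<p class='stub'>no results</p>"

#' Render the static HTML report
#'
#' Scans a results directory (as written by the `run_*` steps, possibly
#' across subdirectories) and assembles one self-contained HTML page:
#' prevalence heatmaps, co-localization / correlation matrices, decoding
#' confusion and attribution matrices, effector composition, regional
#' rankings and AP profiles. Sections whose inputs are absent are
#' rendered as explicit "no results" stubs; an empty directory yields a
#' valid page of stubs.
#'
#' @param results_dir Directory containing step outputs.
#' @param out_file Path of the HTML file to write.
#' @return `out_file`, invisibly.
#' @export
render_report <- function(results_dir, out_file = file.path(results_dir, "report.html")) {
  find1 <- function(pattern) {
    hits <- list.files(results_dir, pattern = pattern, recursive = TRUE,
                       full.names = TRUE)
    if (length(hits) == 0) NULL else sort(hits)
  }
  read1 <- function(path) readr::read_csv(path, show_col_types = FALSE,
                                          progress = FALSE)
  as_matrix <- function(df) {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }

  sections <- character(0)

  prev_files <- find1("^prevalence_.*\\.csv$|/prevalence_.*\\.csv$")
  sections <- c(sections, report_section("Prevalence", if (is.null(prev_files)) stub else {
    paste(vapply(prev_files, function(f) {
      prev <- read1(f)
      attr(prev, "level") <- sub("^prevalence_(.*)\\.csv$", "\\1", basename(f))
      paste0(embed_plot(plot_prevalence_heatmap(prev)), html_table(prev))
    }, character(1)), collapse = "")
  }))

  coloc <- find1("coloc_matrix\\.csv$")
  sections <- c(sections, report_section("Co-localization", if (is.null(coloc)) stub else {
    m <- as_matrix(read1(coloc[1]))
    embed_plot(plot_matrix(m, "Co-localization (%)"))
  }))

  corr <- find1("correlation_matrix\\.csv$")
  sections <- c(sections, report_section("Expression correlation", if (is.null(corr)) stub else {
    embed_plot(plot_matrix(as_matrix(read1(corr[1])), "Pearson r"))
  }))

  conf <- find1("confusion_matrix\\.csv$")
  shap <- find1("attribution_matrix\\.csv$")
  body <- if (is.null(conf) && is.null(shap)) stub else paste0(
    if (!is.null(conf)) embed_plot(plot_matrix(as_matrix(read1(conf[1])),
                                               "True-label fraction")) else "",
    if (!is.null(shap)) embed_plot(plot_matrix(as_matrix(read1(shap[1])),
                                               "Mean |attribution|")) else "")
  sections <- c(sections, report_section("Decoding", body))

  comp <- find1("family_composition_.*\\.csv$")
  sections <- c(sections, report_section("Primary effector families",
    if (is.null(comp)) stub else {
      embed_plot(plot_family_composition(read1(comp[1])))
    }))

  region <- find1("_(division|structure)\\.csv$")
  sections <- c(sections, report_section("Regional prevalence",
    if (is.null(region)) stub else {
      paste(vapply(region, function(f) {
        paste0("<h3>", html_escape(basename(f)), "</h3>", html_table(read1(f)))
      }, character(1)), collapse = "")
    }))

  prof <- find1("_ap_profile\\.csv$")
  sections <- c(sections, report_section("Anteroposterior profiles",
    if (is.null(prof)) stub else {
      paste(vapply(prof, function(f) {
        paste0("<h3>", html_escape(basename(f)), "</h3>",
               embed_plot(plot_ap_profile(read1(f))))
      }, character(1)), collapse = "")
    }))

  page <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Receptor landscape report</title>",
    "<style>body{font-family:sans-serif;max-width:1000px;margin:auto}",
    "table{border-collapse:collapse;font-size:12px}",
    "td,th{border:1px solid #ccc;padding:2px 6px}",
    ".stub{color:#888;font-style:italic}</style></head><body>",
    "<h1>Receptor landscape report</h1>",
    paste(sections, collapse = ""),
    "</body></html>")
  writeLines(page, out_file)
  invisible(out_file)
}
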