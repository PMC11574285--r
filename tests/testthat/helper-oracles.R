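# Independent brute-force oracles: explicit loops, no shared code with the
# implementation. These define what the vectorised statistics must equal.

oracle_prevalence <- function(mask, grp) {
  out <- list()
  for (g in sort(unique(grp))) {
    rows <- which(grp == g)
    for (gene in colnames(mask)) {
      hits <- 0
      for (i in rows) if (mask[i, gene]) hits <- hits + 1
      out[[length(out) + 1]] <- data.frame(
        group = g, gene = gene,
        prevalence = 100 * hits / length(rows),
        n_cells = length(rows))
    }
  }
  do.call(rbind, out)
}

oracle_any <- function(mask, genes) {
  hits <- 0
  for (i in seq_len(nrow(mask))) {
    found <- FALSE
    for (gene in genes) if (mask[i, gene]) found <- TRUE
    if (found) hits <- hits + 1
  }
  100 * hits / nrow(mask)
}

oracle_coloc <- function(mask) {
  genes <- colnames(mask)
  out <- matrix(NA_real_, length(genes), length(genes),
                dimnames = list(genes, genes))
  for (y in genes) {
    n_y <- sum(mask[, y])
    if (n_y == 0) next
    for (x in genes) {
      both <- sum(mask[, y] & mask[, x])
      out[y, x] <- 100 * both / n_y
    }
  }
  out
}

oracle_n_receptors <- function(mask) {
  ks <- integer(nrow(mask))
  for (i in seq_len(nrow(mask))) ks[i] <- sum(mask[i, ])
  lev <- 0:ncol(mask)
  counts <- sapply(lev, function(k) sum(ks == k))
  data.frame(n_genes = lev,
             pct_all_cells = 100 * counts / nrow(mask),
             pct_positive_cells = c(NA, 100 * counts[-1] / sum(ks >= 1)))
}

oracle_family_sums <- function(expr, fmap) {
  out <- matrix(0, nrow(expr), length(fmap),
                dimnames = list(rownames(expr), names(fmap)))
  for (i in seq_len(nrow(expr))) {
    for (f in names(fmap)) {
      s <- 0
      for (g in fmap[[f]]) s <- s + expr[i, g]
      out[i, f] <- s
    }
  }
  out
}

oracle_region_prevalence <- function(flag, region) {
  out <- list()
  for (r in sort(unique(region))) {
    rows <- which(region == r)
    out[[r]] <- 100 * sum(flag[rows]) / length(rows)
  }
  unlist(out)
}

oracle_ap_profile <- function(flag, section, ap) {
  secs <- unique(section)
  means <- sapply(secs, function(s) mean(ap[section == s]))
  secs <- secs[order(means)]
  data.frame(
    section_label = secs,
    prevalence = sapply(secs, function(s) {
      rows <- which(section == s)
      100 * sum(flag[rows]) / length(rows)
    }))
}

# Peak selection by exhaustive candidate enumeration under the same
# local-maximum + pairwise-spacing rule.
oracle_top_sections <- function(prevalence, ap, labels, k, min_spacing) {
  n <- length(prevalence)
  peak <- logical(n)
  for (i in seq_len(n)) {
    lo <- if (i == 1) TRUE else prevalence[i] >= prevalence[i - 1]
    hi <- if (i == n) TRUE else prevalence[i] >= prevalence[i + 1]
    peak[i] <- lo && hi
  }
  pick_greedy <- function(cands, taken_ap, want) {
    chosen <- integer(0)
    for (i in cands) {
      ok <- TRUE
      for (a in taken_ap) if (abs(ap[i] - a) < min_spacing) ok <- FALSE
      if (ok) {
        chosen <- c(chosen, i)
        taken_ap <- c(taken_ap, ap[i])
        if (length(taken_ap) >= want) break
      }
    }
    chosen
  }
  ord <- function(idx) idx[order(-prevalence[idx], ap[idx])]
  sel <- pick_greedy(ord(which(peak)), numeric(0), k)
  if (length(sel) < k) {
    rest <- setdiff(ord(seq_len(n)), sel)
    sel <- c(sel, pick_greedy(rest, ap[sel], k))
  }
  labels[sel[seq_len(min(k, length(sel)))]]
}
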