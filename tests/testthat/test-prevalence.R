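test_that("detection is strict at the boundary and matches elementwise comparison", {
  expr <- matrix(c(3.5, 3.51, 7, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  mask <- detect(expr, thresholds())
  expect_false(mask["a", "g1"])   # boundary value NOT detected under strict >
  expect_true(mask["a", "g2"])
  lax <- detect(expr, thresholds(strict = FALSE))
  expect_true(lax["a", "g1"])

  expect_true(all(!detect(matrix(0, 5, 3, dimnames = list(NULL, c("a", "b", "c"))))))

  big <- rand_expr(100, seed = 12)
  got <- detect(big)
  for (i in seq_len(nrow(big))) {
    for (j in seq_len(ncol(big))) {
      expect_identical(got[i, j], big[i, j] > 3.5)
    }
  }
})

test_that("prevalence by group equals the brute-force loop exactly", {
  # one group, 3 of 4 cells detected -> 75%
  cells4 <- tibble::tibble(cell_label = paste0("c", 1:4), class = "A",
                           subclass = "A", supertype = "A", cluster = "A")
  m4 <- matrix(c(TRUE, TRUE, TRUE, FALSE), 4, 1,
               dimnames = list(cells4$cell_label, "g"))
  expect_equal(prevalence_by_group(m4, cells4, "class")$prevalence, 75)

  cells <- tiny_cells(500, seed = 31)
  mask <- rand_mask(500, seed = 31)
  rownames(mask) <- cells$cell_label
  got <- prevalence_by_group(mask, cells, "class")
  ref <- oracle_prevalence(mask, cells$class)
  got <- got[order(got$group, got$gene), ]
  ref <- ref[order(ref$group, ref$gene), ]
  expect_equal(got$prevalence, ref$prevalence)
  expect_equal(got$n_cells, ref$n_cells)
  expect_error(prevalence_by_group(mask, cells, "nope"), "unknown grouping")
})

test_that("any-gene prevalence matches additivity and the row-wise oracle", {
  # disjoint single-gene masks of 30% and 20% -> 50%
  m <- matrix(FALSE, 100, 2, dimnames = list(NULL, c("g1", "g2")))
  m[1:30, 1] <- TRUE
  m[31:50, 2] <- TRUE
  expect_equal(prevalence_any(m), 50)
  expect_equal(prevalence_any(matrix(FALSE, 10, 2,
    dimnames = list(NULL, c("a", "b")))), 0)

  mask <- rand_mask(400, seed = 44)
  expect_equal(prevalence_any(mask), oracle_any(mask, colnames(mask)))
  expect_equal(prevalence_any(mask, c("Htr1a", "Htr7")),
               oracle_any(mask, c("Htr1a", "Htr7")))
})

test_that("mean amount by group handles detected-only and empty groups", {
  cells <- tibble::tibble(cell_label = c("c1", "c2"), class = c("A", "B"),
                          subclass = "x", supertype = "x", cluster = "x")
  expr <- matrix(c(5, 1), 2, 1, dimnames = list(c("c1", "c2"), "g"))
  mask <- matrix(c(TRUE, FALSE), 2, 1, dimnames = dimnames(expr))
  got <- mean_amount_by_group(expr, mask, cells, "class")
  expect_equal(got$mean_amount[got$group == "A"], 5)
  expect_true(is.na(got$mean_amount[got$group == "B"]))  # no detected cells

  cells <- tiny_cells(300, seed = 9)
  expr <- rand_expr(300, seed = 9)
  rownames(expr) <- cells$cell_label
  mask <- detect(expr, thresholds(detection_scrna = 4))
  got <- mean_amount_by_group(expr, mask, cells, "class")
  for (r in sample(nrow(got), 20)) {
    rows <- cells$class == got$group[r]
    vals <- expr[rows, got$gene[r]][mask[rows, got$gene[r]]]
    ref <- if (length(vals) == 0) NA_real_ else mean(vals)
    expect_equal(got$mean_amount[r], ref)
  }
})

test_that("prevalence-amount shared variance behaves at the extremes", {
  # amounts an exact affine function of prevalence -> R^2 = 1
  n <- 200
  genes <- paste0("g", 1:5)
  expr <- matrix(0, n, 5, dimnames = list(paste0("c", 1:n), genes))
  for (j in 1:5) {
    k <- 20 * j                       # prevalence 10%..50%
    expr[seq_len(k), j] <- 4 + j      # constant amount per gene, affine in j
  }
  mask <- detect(expr)
  expect_equal(prevalence_amount_r2(expr, mask), 1)

  expr2 <- rand_expr(300, seed = 77)
  mask2 <- detect(expr2, thresholds(detection_scrna = 5))
  prev <- 100 * colMeans(mask2)
  amt <- sapply(colnames(expr2), function(g) mean(expr2[mask2[, g], g]))
  expect_equal(prevalence_amount_r2(expr2, mask2), cor(prev, amt)^2)
})

test_that("top groups by count rank descending with lexicographic ties", {
  cells <- tibble::tibble(
    cell_label = paste0("c", 1:9),
    class = c(rep("A", 5), rep("B", 3), "C"),
    subclass = "x", supertype = "x", cluster = "x")
  mask <- matrix(TRUE, 9, 1, dimnames = list(cells$cell_label, "g"))
  got <- top_groups_by_count(mask, cells, "g", "class", k = 2)
  expect_equal(got$group, c("A", "B"))
  expect_equal(got$count, c(5, 3))

  # tie at rank k: lexicographic winner retained
  cells$class <- c(rep("B", 3), rep("A", 3), rep("C", 3))
  got <- top_groups_by_count(mask, cells, "g", "class", k = 1)
  expect_equal(got$group, "A")

  cells <- tiny_cells(300, seed = 15)
  mask <- rand_mask(300, seed = 15)
  rownames(mask) <- cells$cell_label
  got <- top_groups_by_count(mask, cells, "Htr4", "class", k = 3)
  counts <- sapply(sort(unique(cells$class)), function(g) {
    sum(mask[cells$class == g, "Htr4"])
  })
  ref <- counts[order(-counts, names(counts))][1:3]
  expect_equal(got$count, unname(ref))
  expect_equal(got$group, names(ref))
})

test_that("prevalence invariants hold on random fixtures", {
  cells <- tiny_cells(400, seed = 51)
  expr <- rand_expr(400, seed = 51)
  rownames(expr) <- cells$cell_label

  # monotone non-increasing in the detection threshold
  prev_at <- function(thr) {
    mean(prevalence_by_group(detect(expr, thresholds(detection_scrna = thr)),
                             cells, "class")$prevalence)
  }
  ladder <- sapply(c(1, 2, 3.5, 5, 7), prev_at)
  expect_true(all(diff(ladder) <= 0))

  # prevalence over the union equals the count-weighted mean of groups
  mask <- detect(expr)
  prev <- prevalence_by_group(mask, cells, "class")
  for (g in colnames(mask)[1:4]) {
    sub <- prev[prev$gene == g, ]
    pooled <- sum(sub$prevalence * sub$n_cells) / sum(sub$n_cells)
    expect_equal(pooled, 100 * mean(mask[, g]))
  }

  # any-gene prevalence bounded by max single gene and sum of genes
  p_any <- prevalence_any(mask)
  singles <- 100 * colMeans(mask)
  expect_gte(p_any, max(singles))
  expect_lte(p_any, sum(singles))
})
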