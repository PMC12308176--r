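peak_df <- function(...) {
  rows <- list(...)
  data.frame(chrom = vapply(rows, `[[`, "", 1),
             start = as.integer(vapply(rows, `[[`, "", 2)),
             end = as.integer(vapply(rows, `[[`, "", 3)))
}

gene_df <- function(...) {
  rows <- list(...)
  data.frame(gene_id = vapply(rows, `[[`, "", 1),
             chrom = vapply(rows, `[[`, "", 2),
             start = as.integer(vapply(rows, `[[`, "", 3)),
             end = as.integer(vapply(rows, `[[`, "", 4)),
             strand = vapply(rows, `[[`, "", 5))
}

test_that("gene activity sums peak counts over extended gene bodies", {
  # one peak fully inside one gene
  ga <- peaks_to_gene_activity(matrix(5, 1, 1),
                               peak_df(c("chr1", "100", "200")),
                               gene_df(c("g1", "chr1", "0", "1000", "+")))
  expect_equal(unname(ga$values[1, 1]), 5)
  expect_identical(ga$modality, "ATAC")

  # upstream promoter extension, clipped at 0, catches a peak before the TSS
  ga2 <- peaks_to_gene_activity(
    matrix(c(2, 7), 1), peak_df(c("chr1", "0", "50"), c("chr1", "150", "260")),
    gene_df(c("g1", "chr1", "100", "1000", "+")),
    preproc_config(promoter_upstream_bp = 2000))
  expect_equal(unname(ga2$values[1, 1]), 9)
  # without the extension the upstream peak is missed
  ga3 <- peaks_to_gene_activity(
    matrix(c(2, 7), 1), peak_df(c("chr1", "0", "50"), c("chr1", "150", "260")),
    gene_df(c("g1", "chr1", "100", "1000", "+")),
    preproc_config(promoter_upstream_bp = 0))
  expect_equal(unname(ga3$values[1, 1]), 7)

  # on the minus strand the TSS is the right end
  ga4 <- peaks_to_gene_activity(
    matrix(1, 1, 1), peak_df(c("chr1", "1050", "1100")),
    gene_df(c("g1", "chr1", "100", "1000", "-")),
    preproc_config(promoter_upstream_bp = 200))
  expect_equal(unname(ga4$values[1, 1]), 1)

  # a peak shared by two overlapping genes counts in both columns
  ga5 <- peaks_to_gene_activity(
    matrix(3, 1, 1), peak_df(c("chr1", "500", "600")),
    gene_df(c("g1", "chr1", "0", "800", "+"), c("g2", "chr1", "400", "900", "+")),
    preproc_config(promoter_upstream_bp = 0))
  expect_equal(unname(ga5$values[1, ]), c(3, 3))
})

test_that("gene activity matches a brute-force interval oracle", {
  set.seed(21)
  n_cells <- 7; n_peaks <- 40; n_genes <- 12
  starts <- sample.int(5000, n_peaks)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), n_peaks, TRUE),
                      start = starts, end = starts + sample.int(300, n_peaks))
  gs <- sample.int(4500, n_genes)
  genes <- data.frame(gene_id = paste0("g", seq_len(n_genes)),
                      chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                      start = gs, end = gs + sample.int(800, n_genes),
                      strand = sample(c("+", "-"), n_genes, TRUE))
  counts <- matrix(rpois(n_cells * n_peaks, 2), n_cells)
  up <- 500L
  ga <- peaks_to_gene_activity(counts, peaks, genes,
                               preproc_config(promoter_upstream_bp = up))
  for (g in seq_len(n_genes)) {
    lo <- if (genes$strand[g] == "+") max(genes$start[g] - up, 0) else genes$start[g]
    hi <- if (genes$strand[g] == "+") genes$end[g] else genes$end[g] + up
    expected <- rep(0, n_cells)
    for (p in seq_len(n_peaks)) {
      if (peaks$chrom[p] == genes$chrom[g] &&
          peaks$start[p] < hi && peaks$end[p] > lo)
        expected <- expected + counts[, p]
    }
    expect_equal(unname(ga$values[, g]), expected)
  }
})

test_that("gene activity handles empty and disjoint annotations", {
  expect_error(peaks_to_gene_activity(matrix(1, 1, 1),
                                      peak_df(c("chr1", "0", "10")),
                                      gene_df()[0, ]),
               "empty gene annotation")
  expect_warning(
    ga <- peaks_to_gene_activity(matrix(4, 1, 1),
                                 peak_df(c("chrX", "0", "10")),
                                 gene_df(c("g1", "chr1", "0", "100", "+"))),
    "no chromosome shared")
  expect_true(all(ga$values == 0))
})

test_that("normalize_log scales cells to the target then applies log1p", {
  cfg <- preproc_config(target_sum = 4)
  m <- cell_matrix(matrix(c(1, 3), 1), "c1", c("g1", "g2"), "RNA")
  out <- normalize_log(m, cfg)
  expect_equal(unname(out$values[1, ]), c(log(2), log(4)))

  one <- cell_matrix(matrix(7, 1, 1), "c1", "g1", "RNA")
  expect_equal(unname(normalize_log(one, preproc_config(target_sum = 7))$values[1, 1]),
               log(1 + 7))

  z <- cell_matrix(matrix(c(0, 0, 1, 1), 2, byrow = TRUE), c("c1", "c2"),
                   c("g1", "g2"), "RNA")
  expect_warning(outz <- normalize_log(z, cfg), "zero total count.*c1")
  expect_equal(unname(outz$values[1, ]), c(0, 0))

  neg <- cell_matrix(matrix(c(-1, 2), 1), "c1", c("g1", "g2"), "RNA")
  expect_error(normalize_log(neg, cfg), "non-negative")
})

test_that("normalize_log is monotone within each cell", {
  set.seed(4)
  m <- cell_matrix(matrix(rpois(60, 5), 6), paste0("c", 1:6),
                   paste0("g", 1:10), "RNA")
  out <- normalize_log(m, preproc_config())
  for (i in 1:6)
    expect_identical(order(out$values[i, ]), order(m$values[i, ]))
})

test_that("select_hvg ranks by the dispersion statistic with id tie-breaks", {
  v <- cbind(a = c(0, 0, 0, 0), b = c(-2, 2, -2, 2), c = c(-1, 1, -1, 1),
             d = c(-3, 3, -3, 3), e = c(0.5, -0.5, 0.5, -0.5))
  m <- cell_matrix(v, paste0("c", 1:4), colnames(v), "RNA")
  top2 <- select_hvg(m, 2)
  vars <- apply(v, 2, var)
  expect_identical(top2$feature_ids,
                   names(sort(vars, decreasing = TRUE))[1:2])
  # constant feature is never selected ahead of any varying one
  expect_false("a" %in% select_hvg(m, 4)$feature_ids)
  # n_hvg = n_features keeps the full set (reordered by dispersion)
  expect_setequal(select_hvg(m, 5)$feature_ids, colnames(v))
  expect_warning(all6 <- select_hvg(m, 6), "keeping all")
  expect_equal(ncol(all6$values), 5)
  # exact ties fall back to feature id order
  tied <- cell_matrix(cbind(z = c(-1, 1), y = c(1, -1), x = c(-1, 1)),
                      c("c1", "c2"), c("z", "y", "x"), "RNA")
  expect_identical(select_hvg(tied, 2)$feature_ids, c("x", "y"))
})

test_that("scale_features standardises with the population denominator", {
  m <- cell_matrix(cbind(a = c(1, 1, 1), b = c(0, 2, 4)), paste0("c", 1:3),
                   c("a", "b"), "RNA")
  out <- scale_features(m)
  expect_equal(unname(out$values[, "a"]), c(0, 0, 0))
  # population sd of (0,2,4) is sqrt(8/3)
  expect_equal(unname(out$values[, "b"]), (c(0, 2, 4) - 2) / sqrt(8 / 3))

  two <- cell_matrix(cbind(b = c(0, 2)), c("c1", "c2"), "b", "RNA")
  expect_equal(unname(scale_features(two)$values[, 1]), c(-1, 1))
  expect_equal(unname(scale_features(two, scale_clip = 0.5)$values[, 1]),
               c(-0.5, 0.5))

  set.seed(8)
  r <- cell_matrix(matrix(rnorm(200, 5, 2), 20), paste0("c", 1:20),
                   paste0("g", 1:10), "RNA")
  expect_lt(max(abs(colMeans(scale_features(r)$values))), 1e-9)
})

test_that("reduce_pca returns deterministic sign-fixed scores", {
  # 2-D data with one zero-variance axis: the single score is the other axis
  m <- cell_matrix(cbind(x = c(-2, 0, 2), y = c(1, 1, 1)), paste0("c", 1:3),
                   c("x", "y"), "RNA")
  sc <- reduce_pca(m, 1)
  expect_equal(unname(sc$values[, 1]), c(-2, 0, 2))
  expect_identical(sc$feature_ids, "PC1")

  set.seed(12)
  r <- matrix(rnorm(500), 50, 10)
  rm <- cell_matrix(r, paste0("c", 1:50), paste0("g", 1:10), "RNA")
  k <- 4
  sc4 <- reduce_pca(rm, k)
  # projection never gains variance
  expect_lte(sum(apply(sc4$values, 2, var)), sum(apply(r, 2, var)) + 1e-12)
  # reconstruction error from top-k equals the discarded eigenvalue mass
  xc <- scale(r, scale = FALSE)
  ev <- eigen(crossprod(xc), symmetric = TRUE)$values
  s <- svd(xc)
  recon <- s$u[, 1:k] %*% diag(s$d[1:k]) %*% t(s$v[, 1:k])
  expect_equal(sum((xc - recon)^2), sum(ev[(k + 1):10]), tolerance = 1e-8)
  expect_error(reduce_pca(rm, 11), "n_pca")
})

test_that("reduce_pca is invariant to feature permutation", {
  set.seed(13)
  r <- matrix(rnorm(300), 30, 10)
  m1 <- cell_matrix(r, paste0("c", 1:30), paste0("g", 1:10), "RNA")
  perm <- sample(10)
  m2 <- cell_matrix(r[, perm], paste0("c", 1:30), paste0("g", 1:10)[perm],
                    "RNA")
  expect_equal(unname(reduce_pca(m1, 3)$values),
               unname(reduce_pca(m2, 3)$values), tolerance = 1e-8)
})

test_that("the preprocessing pipeline preserves cell order and ids", {
  ds <- tiny_sim(seed = 6)
  out <- suppressWarnings(preprocess_matrix(ds$rna,
                                            preproc_config(n_hvg = 60,
                                                           n_pca = 10)))
  expect_identical(out$cell_ids, ds$rna$cell_ids)
  expect_equal(dim(out$values), c(120L, 10L))
})
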