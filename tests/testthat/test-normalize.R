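count_matrix <- function(values, lsp = NULL) {
  values <- as.matrix(values)
  expr_matrix(values, paste0("g", seq_len(nrow(values))),
              paste0("s", seq_len(ncol(values))), "raw_count",
              library_size_proxy = lsp)
}

test_that("the low-expression filter removes floor(fraction * n) genes", {
  m <- count_matrix(cbind(1:10, 0))
  f <- filter_low_expression(m, 0.3)
  expect_identical(nrow(f$kept$values), 7L)
  expect_identical(f$removed, paste0("g", 1:3))
  expect_identical(filter_low_expression(m, 0)$kept$gene_names, m$gene_names)
  expect_error(filter_low_expression(m, 1), "fraction")
  expect_error(filter_low_expression(log_transform(m), 0.3), "raw counts")
})

test_that("filter ties break by original row order and survivors keep order", {
  m <- count_matrix(cbind(c(5, 1, 1, 1, 9), 0))
  f <- filter_low_expression(m, 0.4)   # drops 2 of the three tied at 1
  expect_identical(f$removed, c("g2", "g3"))
  expect_identical(f$kept$gene_names, c("g1", "g4", "g5"))
})

test_that("14,744 genes minus 30% minus 12 mitochondrial leaves 10,309", {
  set.seed(2)
  totals <- sample.int(5e5, 14744)
  m <- count_matrix(cbind(totals, 0L))
  mito <- m$gene_names[order(totals, decreasing = TRUE)[1:12]]
  f <- filter_low_expression(m, 0.3)
  expect_identical(nrow(f$kept$values), 14744L - 4423L)
  g <- remove_genes(f$kept, mito)
  expect_identical(nrow(g$kept$values), 10309L)
  expect_identical(length(g$removed), 12L)
})

test_that("removing absent genes warns and is a no-op; empty list identity", {
  m <- count_matrix(cbind(1:5, 1))
  expect_warning(out <- remove_genes(m, c("g2", "nope")), "not present")
  expect_identical(out$kept$gene_names, c("g1", "g3", "g4", "g5"))
  expect_identical(remove_genes(m, character())$kept$gene_names, m$gene_names)
})

test_that("filter and mitochondrial removal commute when mito genes rank in
          the retained stratum (drop count held fixed)", {
  set.seed(3)
  m <- count_matrix(matrix(rnbinom(200 * 4, mu = 50, size = 5), 200, 4))
  mito <- m$gene_names[order(rowSums(m$values), decreasing = TRUE)[1:5]]
  a <- remove_genes(filter_low_expression(m, 0.3)$kept, mito)$kept
  pre <- remove_genes(m, mito)$kept
  # same absolute drop count (60) applied to the 195 remaining genes
  b <- filter_low_expression(pre, 60 / 195)$kept
  expect_identical(sort(a$gene_names), sort(b$gene_names))
})

gc_vec <- function(m, gc) setNames(gc, m$gene_names)

test_that("GC normalization leaves unbiased columns essentially unchanged", {
  set.seed(14)
  n <- 1000
  gc <- runif(n, 0.3, 0.7)
  counts <- matrix(rnbinom(n * 2, mu = 200, size = 10), n, 2)
  m <- count_matrix(counts)
  out <- gc_normalize_within_sample(m, gc_vec(m, gc))
  expect_lt(abs(sum(out$values[, 1]) / sum(counts[, 1]) - 1), 0.01)
  # within-bin rank preservation
  bin <- ceiling(rank(gc, ties.method = "first") * 10 / n)
  for (b in c(1, 5, 10)) {
    idx <- bin == b
    expect_gte(cor(rank(counts[idx, 1]), rank(out$values[idx, 1]),
                   method = "spearman"), 0.99)
  }
})

test_that("planted monotone GC bias is removed by full-quantile matching", {
  set.seed(15)
  n <- 2000
  gc <- 0.2 + 0.6 * rbeta(n, 2, 2)
  mu <- 150 * exp(3 * (gc - 0.5))
  counts <- matrix(rnbinom(n * 2, mu = mu, size = 10), n, 2)
  m <- count_matrix(counts)
  expect_gt(abs(gc_bias_correlation(counts[, 1], gc)), 0.9)
  out_fq <- gc_normalize_within_sample(m, gc_vec(m, gc))
  expect_lt(abs(gc_bias_correlation(out_fq$values[, 1], gc)), 0.1)
  # median/loess adjust a location summary per stratum, so a small
  # shape-driven residual remains on the bin-mean diagnostic
  for (method in c("median", "loess")) {
    out <- gc_normalize_within_sample(m, gc_vec(m, gc), method = method)
    expect_lt(abs(gc_bias_correlation(out$values[, 1], gc)), 0.5)
  }
})

test_that("GC normalization is column-independent and deterministic", {
  set.seed(16)
  n <- 400
  gc <- runif(n)
  counts <- cbind(a = rnbinom(n, mu = 80, size = 5))
  m2 <- count_matrix(cbind(counts, counts, rnbinom(n, mu = 10, size = 2)))
  out <- gc_normalize_within_sample(m2, gc_vec(m2, gc))
  expect_identical(out$values[, 1], out$values[, 2])
  expect_error(gc_normalize_within_sample(m2, gc_vec(m2, gc), num_bins = 1),
               "num_bins")
  gc_missing <- gc_vec(m2, gc)[-1]
  expect_error(gc_normalize_within_sample(m2, gc_missing), "lacking")
})

test_that("TMM factors are 1 for identical columns and ignore column scaling", {
  set.seed(30)
  col <- rnbinom(60, mu = 80, size = 5) + 1
  m <- count_matrix(matrix(rep(col, 3), ncol = 3))
  expect_equal(unname(tmm_factors(m)$tmm_factor), rep(1, 3))
  set.seed(17)
  y2 <- matrix(rnbinom(400 * 3, mu = 100, size = 8), 400, 3)
  f1 <- tmm_factors(count_matrix(y2))
  y2[, 2] <- y2[, 2] * 4
  f2 <- tmm_factors(count_matrix(y2))
  # M, A and the trim set are exactly scale-invariant; the inverse-variance
  # weights are not (their column term scales, the reference term does
  # not), so invariance holds closely but not bit-exactly
  expect_equal(f1$tmm_factor, f2$tmm_factor, tolerance = 0.02)
})

test_that("TMM matches the step-by-step oracle to 1e-10 and edgeR agrees", {
  for (seed in c(18, 19, 20)) {
    set.seed(seed)
    y <- matrix(rnbinom(200 * 4, mu = exp(rnorm(200, 4, 1)), size = 3), 200, 4)
    y[1, ] <- 0          # an all-zero gene must not disturb anything
    m <- count_matrix(y)
    f <- tmm_factors(m)
    expect_equal(unname(f$tmm_factor), oracle_tmm(y), tolerance = 1e-10)
    er <- edgeR::calcNormFactors(y, method = "TMM")
    expect_equal(unname(f$tmm_factor), unname(er), tolerance = 1e-8)
  }
})

test_that("TMM is gene-permutation invariant and sample-swap equivariant", {
  set.seed(21)
  y <- matrix(rnbinom(300 * 4, mu = 120, size = 6), 300, 4)
  f <- tmm_factors(count_matrix(y))$tmm_factor
  fp <- tmm_factors(count_matrix(y[sample.int(300), ]))$tmm_factor
  expect_equal(unname(f), unname(fp), tolerance = 1e-12)
  ys <- y[, c(2, 1, 3, 4)]
  fs <- tmm_factors(count_matrix(ys))$tmm_factor
  expect_equal(unname(fs), unname(f)[c(2, 1, 3, 4)], tolerance = 1e-12)
})

test_that("TMM refuses all-zero columns and product of factors is 1", {
  y <- matrix(c(0, 0, 0, 1, 2, 3), 3, 2)
  expect_error(tmm_factors(count_matrix(y)), "all-zero")
  set.seed(22)
  y2 <- matrix(rnbinom(500 * 5, mu = 90, size = 4), 500, 5)
  f <- tmm_factors(count_matrix(y2))$tmm_factor
  expect_equal(prod(f), 1, tolerance = 1e-12)
})

test_that("depth normalization scales columns by effective library size", {
  y <- matrix(c(10, 20, 30, 20, 40, 60), 3, 2)
  m <- count_matrix(y, lsp = c(s1 = 100, s2 = 200))
  fac <- list(effective_library_size = c(s1 = 100, s2 = 200))
  out <- depth_normalize(m, fac)
  expect_equal(out$values[, "s2"], out$values[, "s1"])  # doubled size halves
  eq <- depth_normalize(count_matrix(y, lsp = c(s1 = 7, s2 = 7)),
                        list(effective_library_size = c(s1 = 7, s2 = 7)))
  expect_equal(eq$values, m$values, ignore_attr = TRUE)
  # size-weighted column sums equalize when all genes are retained
  set.seed(23)
  y3 <- matrix(rnbinom(200 * 4, mu = 50, size = 5), 200, 4)
  m3 <- count_matrix(y3, lsp = setNames(colSums(y3), paste0("s", 1:4)))
  f3 <- tmm_factors(m3)
  d3 <- depth_normalize(m3, f3)
  w <- colSums(d3$values) * f3$tmm_factor
  expect_lt(max(abs(w - mean(w))) / mean(w), 1e-9)
  expect_error(depth_normalize(m3, list(effective_library_size =
    setNames(c(0, 1, 1, 1), paste0("s", 1:4)))), "non-positive")
})

test_that("log transform applies log2(x + 1) and rejects negatives", {
  m <- count_matrix(cbind(c(0, 1, 7), c(3, 0, 15)))
  out <- log_transform(m)
  expect_equal(unname(out$values[, 1]), c(0, 1, 3))
  expect_equal(unname(out$values[, 2]), c(2, 0, 4))
  expect_identical(out$value_kind, "log2")
  bad <- m; bad$values[1, 1] <- -1
  expect_error(log_transform(bad), "negative")
})
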