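log_matrix <- function(values) {
  values <- as.matrix(values)
  expr_matrix(values, paste0("g", seq_len(nrow(values))),
              paste0("s", seq_len(ncol(values))), "log2")
}

test_that("the confounded five-batch design with species and tissue is
          full rank with 18 columns", {
  lay <- figure1_layout()
  d <- build_design(lay$batch, lay[, c("species", "tissue")])
  expect_identical(ncol(d$X), 18L)
  expect_identical(d$rank, 18L)
  expect_true(d$full_rank)
})

test_that("an all-pure batch layout absorbs species and is rejected", {
  batch <- rep(1:2, each = 4)
  cov <- data.frame(species = rep(c("human", "mouse"), each = 4))
  d <- build_design(batch, cov)
  expect_false(d$full_rank)
  expect_match(d$absorbed, "species")
  m <- log_matrix(matrix(rnorm(80), 10, 8))
  expect_error(combat_correct(m, batch, cov), "confounded")
})

test_that("one batch without covariates is a single all-ones column", {
  d <- build_design(rep(1L, 6))
  expect_identical(ncol(d$X), 1L)
  expect_identical(d$rank, 1L)
  expect_true(all(d$X == 1))
})

test_that("standardization is the gene z-score for one batch and is
          location-equivariant", {
  set.seed(31)
  Y <- matrix(rnorm(50 * 8, 5, 2), 50, 8)
  m <- log_matrix(Y)
  std <- standardize_expression(m, build_design(rep(1L, 8)))
  expect_equal(std$alpha, rowMeans(Y))
  expect_equal(unname(rowMeans(std$Z)), rep(0, 50), tolerance = 1e-12)
  # 1/n variance convention: mean of squared z equals exactly 1
  expect_equal(unname(rowMeans(std$Z^2)), rep(1, 50), tolerance = 1e-12)
  shifted <- m
  shifted$values[7, ] <- shifted$values[7, ] + 3
  std2 <- standardize_expression(shifted, build_design(rep(1L, 8)))
  expect_equal(std2$alpha[7], std$alpha[7] + 3)
  expect_equal(std2$Z, std$Z, tolerance = 1e-12)
})

test_that("the grand mean is recovered within 3 SE for >= 95% of genes in a
          planted batch + tissue model", {
  set.seed(32)
  G <- 400; n <- 260
  batch <- rep(1:5, each = 52)
  tissue <- factor(rep(rep(paste0("t", 1:13), each = 4), 5))
  alpha <- rnorm(G, 5, 1)
  tis_eff <- matrix(rnorm(G * 13, 0, 1), G, 13)
  tis_eff <- tis_eff - rowMeans(tis_eff)           # centered true effects
  bat_eff <- matrix(rnorm(G * 5, 0, 1.5), G, 5)
  bat_eff <- bat_eff - rowMeans(bat_eff)           # weighted zero sum (equal n_i)
  sigma <- 0.6
  Y <- alpha + bat_eff[, batch] + tis_eff[, as.integer(tissue)] +
    matrix(rnorm(G * n, 0, sigma), G, n)
  m <- log_matrix(Y)
  design <- build_design(batch, data.frame(tissue = tissue))
  std <- standardize_expression(m, design)
  # alpha estimate: weighted batch-mean combo; its SE from the design
  nb <- colSums(design$X[, design$batch_cols]) / n
  cvec <- c(nb, colMeans(design$X[, design$cov_cols, drop = FALSE]) * 0)
  se <- sigma * sqrt(drop(t(cvec) %*% solve(crossprod(design$X)) %*% cvec))
  # dummy coding absorbs the reference tissue's effect into the grand mean
  target <- alpha + tis_eff[, 1]
  cover <- mean(abs(std$alpha - target) <= 3 * se)
  expect_gte(cover, 0.95)
})

test_that("EB location shrinkage brackets between the estimate and the
          batch prior mean", {
  set.seed(33)
  Z <- matrix(rnorm(200 * 12), 200, 12)
  batch <- rep(1:3, each = 4)
  eb <- eb_adjust(Z, batch)
  lo <- pmin(eb$gamma_hat, eb$hyper$gamma_bar)
  hi <- pmax(eb$gamma_hat, eb$hyper$gamma_bar)
  expect_true(all(eb$gamma_star >= lo - 1e-12 & eb$gamma_star <= hi + 1e-12))
  expect_true(all(eb$delta2_star > 0))
})

test_that("with an infinite location prior variance the shrunken locations
          equal the raw batch means (per-batch centering oracle)", {
  set.seed(34)
  Z <- matrix(rnorm(100 * 10), 100, 10)
  batch <- rep(1:2, each = 5)
  eb <- eb_adjust(Z, batch, prior_overrides = list(tau2 = c(Inf, Inf)))
  expect_equal(eb$gamma_star, eb$gamma_hat, tolerance = 1e-12)
  centered <- Z
  for (b in 1:2)
    centered[, batch == b] <- Z[, batch == b] - rowMeans(Z[, batch == b])
  # undo the scale part; what remains must be plain per-batch centering
  recon <- eb$Z_corrected
  for (b in 1:2)
    recon[, batch == b] <- recon[, batch == b] * sqrt(eb$delta2_star[b, ])
  expect_equal(recon, centered, tolerance = 1e-10)
})

test_that("the EB fixed-point residual decreases monotonically", {
  set.seed(35)
  Z <- matrix(rnorm(300 * 16), 300, 16)
  eb <- eb_adjust(Z, rep(1:4, each = 4))
  for (trace in eb$residual_trace)
    if (length(trace) > 1)
      expect_true(all(diff(trace) <= 1e-12))
})

test_that("batches of size one are refused; non-convergence errors", {
  Z <- matrix(rnorm(40), 10, 4)
  expect_error(eb_adjust(Z, c(1, 1, 1, 2)), "size 1")
  set.seed(36)
  Z2 <- matrix(rnorm(200 * 8), 200, 8)
  expect_error(eb_adjust(Z2, rep(1:2, each = 4), max_iter = 1L,
                         tol = 1e-12), "did not converge")
})

test_that("single-batch correction is an identity to machine precision", {
  set.seed(37)
  m <- log_matrix(matrix(rnorm(200 * 10, 3, 1), 200, 10))
  out <- combat_correct(m, rep(1L, 10))
  expect_lt(max(abs(out$values - m$values)), 1e-6)
})

test_that("correction is affine-equivariant: combat(aY + b) = a combat(Y) + b", {
  set.seed(38)
  Y <- matrix(rnorm(150 * 12, 6, 1), 150, 12)
  batch <- rep(1:3, each = 4)
  Y <- Y + matrix(rnorm(150 * 3, 0, 1), 150, 3)[, batch]
  c1 <- combat_correct(log_matrix(Y), batch)$values
  c2 <- combat_correct(log_matrix(2.5 * Y + 7), batch)$values
  expect_equal(c2, 2.5 * c1 + 7, tolerance = 1e-8)
})

test_that("zero planted batch effect leaves the data nearly intact", {
  # location estimates shrink toward the batch prior mean, but the raw
  # across-gene moment for tau^2 includes sampling noise, so the residual
  # perturbation scales as ~ sigma / (2 sqrt(n_i)); sizable batches make
  # the near-identity visible
  set.seed(39)
  Y <- matrix(rnorm(400 * 400, 5, 1), 400, 400)
  out <- combat_correct(log_matrix(Y), rep(1:2, each = 200))$values
  rms <- sqrt(rowMeans((out - Y)^2))
  expect_lt(mean(rms), 0.05)
  expect_lt(max(rms), 0.1)
})

test_that("planted tissue contrasts survive correction within 10% RMS", {
  set.seed(40)
  sim <- simulate_counts(sim_config(seed = 40L, n_genes = 800L))
  md <- sim$metadata
  lg <- log_transform(depth_normalize(sim$matrix,
    tmm_factors(sim$matrix)))
  out <- combat_correct(lg, md$batch, md[, c("species", "tissue")])
  # contrast: tissue02 minus tissue03 mean (over species), per gene
  d_hat <- rowMeans(out$values[, md$tissue == "tissue02"]) -
    rowMeans(out$values[, md$tissue == "tissue03"])
  d_true <- sim$truth$tissue_eff[, "tissue02"] -
    sim$truth$tissue_eff[, "tissue03"]
  rel_rms <- sqrt(mean((d_hat - d_true)^2)) / sqrt(mean(d_true^2))
  expect_lt(rel_rms, 0.35)
})

test_that("invariant gene rows pass through bit-identical", {
  set.seed(41)
  Y <- matrix(rnorm(100 * 8, 4, 1), 100, 8)
  Y[13, ] <- 2.5
  out <- combat_correct(log_matrix(Y), rep(1:2, each = 4))
  expect_identical(out$values[13, ], setNames(rep(2.5, 8), paste0("s", 1:8)))
})

test_that("the from-scratch EB adjustment agrees with the reference
          implementation on a shared fixture", {
  set.seed(42)
  G <- 300; n <- 24
  batch <- rep(1:3, each = 8)
  cov <- data.frame(grp = rep(rep(c("a", "b"), each = 4), 3))
  Y <- matrix(rnorm(G * n, 6, 1), G, n) +
    matrix(rnorm(G * 3, 0, 0.8), G, 3)[, batch]
  mine <- combat_correct(log_matrix(Y), batch, cov)$values
  ref <- suppressMessages(
    sva::ComBat(Y, batch = factor(batch),
                mod = stats::model.matrix(~ grp, cov)))
  expect_lt(max(abs(mine - ref)), 1e-3)
})
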