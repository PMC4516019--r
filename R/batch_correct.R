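#' Parametric empirical-Bayes batch adjustment
#'
#' A from-first-principles implementation of location/scale batch correction
#' on log-scale expression data. The model for gene \eqn{g} in sample
#' \eqn{j} of batch \eqn{i} is
#' \deqn{Y_{jg} = \alpha_g + X_j \beta_g + \gamma_{ig} + \delta_{ig} \epsilon_{jg},}
#' with \eqn{\alpha_g} the grand mean, \eqn{X \beta_g} biological covariate
#' effects (species, tissue), \eqn{\gamma_{ig}} an additive and
#' \eqn{\delta_{ig}} a multiplicative batch effect. Per-batch per-gene
#' estimates are shrunk across genes toward parametric priors — normal for
#' locations, inverse-gamma for scales, hyperparameters by method of
#' moments — via a coupled fixed-point iteration, then removed.
#'
#' The design matrix is checked for rank first: when every batch is pure for
#' a covariate (complete confounding) the covariate is linearly absorbed by
#' the batch indicators and no adjustment can separate the two; the fit is
#' refused with a diagnosis rather than silently absorbing the biology.
#'
#' @name batch_correct
NULL

#' Build and rank-check the batch + covariate design matrix
#'
#' @param batch integer vector of batch labels (1..B), one per sample.
#' @param covariates optional data.frame of categorical covariates (one row
#'   per sample), dummy-coded with the first level as reference.
#' @return list with `X` (full design: B batch indicators, no intercept,
#'   then covariate dummies), `batch_cols`, `cov_cols`, `rank`,
#'   `full_rank`, and — when rank-deficient — `absorbed` naming covariate
#'   columns lying in the span of the batch indicators.
#' @export
build_design <- function(batch, covariates = NULL) {
  batch <- as.integer(batch)
  if (any(is.na(batch))) stop("missing batch label")
  n <- length(batch)
  levels <- sort(unique(batch))
  B <- length(levels)
  Xb <- outer(batch, levels, `==`) + 0
  colnames(Xb) <- paste0("batch", levels)
  Xc <- NULL
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0L) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates/batch length mismatch")
    covariates[] <- lapply(covariates, factor)
    Xc <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
  }
  X <- cbind(Xb, Xc)
  r <- qr(X)$rank
  full <- r == ncol(X)
  absorbed <- character()
  if (!full && !is.null(Xc)) {
    # a covariate column inside the span of the batch indicators is the
    # signature of complete confounding
    for (cc in colnames(Xc)) {
      res <- stats::lm.fit(Xb, Xc[, cc])$residuals
      if (sum(res^2) < 1e-10) absorbed <- c(absorbed, cc)
    }
  }
  list(X = X, batch_cols = seq_len(B),
       cov_cols = if (is.null(Xc)) integer() else B + seq_len(ncol(Xc)),
       n_batches = B, rank = r, full_rank = full, absorbed = absorbed)
}

#' Standardize expression data against the batch + covariate model
#'
#' Per gene, the full model is fit by least squares with the batch effects
#' constrained to a batch-size-weighted zero sum, giving a grand mean
#' \eqn{\alpha_g}, covariate part \eqn{X \beta_g} and pooled variance
#' \eqn{\sigma^2_g} (mean squared residual, dividing by n). The
#' standardized data \eqn{Z = (Y - \alpha - X\beta)/\sigma} retain only the
#' batch effects plus unit-scale noise.
#'
#' @param m an [expr_matrix()], typically `value_kind = "log2"`.
#' @param design result of [build_design()]; must be full rank and have
#'   fewer columns than samples.
#' @return list with `Z` (genes x samples), `alpha`, `beta` (coefficient
#'   matrix, possibly 0-row), `cov_part` (genes x samples), `sigma`, and
#'   `invariant` (logical; genes with zero residual variance, excluded from
#'   EB and passed through unchanged).
#' @export
standardize_expression <- function(m, design) {
  stopifnot(inherits(m, "expr_matrix"))
  if (!design$full_rank)
    stop("design matrix is rank-deficient",
         if (length(design$absorbed))
           paste0(": covariate column(s) fully absorbed by batch: ",
                  paste(design$absorbed, collapse = ", "),
                  " — batch and this factor are completely confounded")
         else "")
  X <- design$X
  n <- nrow(X)
  if (n <= ncol(X)) stop("need more samples than design columns")
  Y <- m$values                          # G x n
  Bhat <- solve(crossprod(X), crossprod(X, t(Y)))   # p x G
  nb <- colSums(X[, design$batch_cols, drop = FALSE])
  alpha <- as.numeric(crossprod(Bhat[design$batch_cols, , drop = FALSE],
                                nb / n))             # weighted mean of batch means
  if (length(design$cov_cols)) {
    beta <- Bhat[design$cov_cols, , drop = FALSE]    # q x G
    cov_part <- t(X[, design$cov_cols, drop = FALSE] %*% beta)  # G x n
  } else {
    beta <- matrix(0, 0, nrow(Y))
    cov_part <- matrix(0, nrow(Y), n)
  }
  resid <- Y - t(X %*% Bhat)
  sigma2 <- rowMeans(resid^2)
  invariant <- sigma2 == 0
  sigma <- sqrt(sigma2)
  Z <- (Y - alpha - cov_part) / ifelse(invariant, 1, sigma)
  list(Z = Z, alpha = alpha, beta = beta, cov_part = cov_part,
       sigma = sigma, invariant = invariant)
}

#' Empirical-Bayes shrinkage and removal of batch effects
#'
#' On standardized data, per-batch per-gene location estimates (batch
#' means) and scale estimates (batch variances, n_i - 1 denominator) are
#' shrunk toward method-of-moments priors — \eqn{\gamma_{ig} \sim
#' N(\bar\gamma_i, \tau^2_i)}, \eqn{\delta^2_{ig} \sim}
#' inverse-gamma\eqn{(\lambda_i, \theta_i)} — by iterating
#' \deqn{\gamma^*_{ig} = \frac{n_i \tau^2_i \hat\gamma_{ig} + \delta^{*2}_{ig} \bar\gamma_i}{n_i \tau^2_i + \delta^{*2}_{ig}}, \qquad
#'       \delta^{*2}_{ig} = \frac{\theta_i + \tfrac12 \sum_{j \in i} (Z_{jg} - \gamma^*_{ig})^2}{n_i/2 + \lambda_i - 1}}
#' to convergence (max absolute change below `tol`).
#'
#' @param Z standardized genes x samples matrix.
#' @param batch integer batch labels, one per sample; every batch needs at
#'   least 2 samples.
#' @param tol fixed-point convergence tolerance (max absolute change).
#' @param max_iter iteration cap; non-convergence is an error.
#' @param prior_overrides optional list for diagnostics/testing: any of
#'   `gamma_bar`, `tau2`, `lambda`, `theta` (each a vector over batches)
#'   replaces the moment estimates.
#' @return list with `Z_corrected`, `gamma_hat`, `delta2_hat`,
#'   `gamma_star`, `delta2_star` (B x G matrices), `hyper` (per-batch
#'   prior hyperparameters), `iterations` (per batch) and
#'   `residual_trace` (per batch, the max-change sequence).
#' @export
eb_adjust <- function(Z, batch, tol = 1e-4, max_iter = 500L,
                      prior_overrides = NULL) {
  batch <- as.integer(batch)
  batches <- sort(unique(batch))
  B <- length(batches)
  G <- nrow(Z)
  sizes <- table(factor(batch, levels = batches))
  if (any(sizes < 2L))
    stop("batch(es) of size 1 — scale effect not estimable: ",
         paste(batches[sizes < 2L], collapse = ", "))
  gamma_hat <- matrix(NA_real_, B, G)
  delta2_hat <- matrix(NA_real_, B, G)
  for (bi in seq_len(B)) {
    Zi <- Z[, batch == batches[bi], drop = FALSE]
    gamma_hat[bi, ] <- rowMeans(Zi)
    delta2_hat[bi, ] <- apply(Zi, 1L, stats::var)
    if (all(delta2_hat[bi, ] < 1e-12))
      stop("batch ", batches[bi], " has no residual variation on any gene ",
           "(the model interpolates it exactly); its scale effect is not ",
           "estimable — enlarge the batch or drop covariates")
  }
  ov <- function(nm, default) {
    if (!is.null(prior_overrides[[nm]])) prior_overrides[[nm]] else default
  }
  gamma_bar <- ov("gamma_bar", rowMeans(gamma_hat))
  tau2 <- ov("tau2", apply(gamma_hat, 1L, stats::var))
  m_d <- rowMeans(delta2_hat)
  s2_d <- apply(delta2_hat, 1L, stats::var)
  # a point-mass empirical distribution (zero spread across genes) breaks
  # the inverse-gamma moment equations; fall back to no shrinkage there
  scale_degenerate <- s2_d < 1e-12
  lambda <- ov("lambda", ifelse(scale_degenerate, Inf,
                                (2 * s2_d + m_d^2) / s2_d))
  theta <- ov("theta", ifelse(scale_degenerate, Inf,
                              (m_d * s2_d + m_d^3) / s2_d))
  loc_degenerate <- tau2 < 1e-12

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  iterations <- integer(B)
  residual_trace <- vector("list", B)
  Zc <- Z
  for (bi in seq_len(B)) {
    in_b <- batch == batches[bi]
    n_i <- sum(in_b)
    Zi <- Z[, in_b, drop = FALSE]
    g_old <- gamma_hat[bi, ]
    d_old <- delta2_hat[bi, ]
    trace <- numeric()
    it <- 0L
    repeat {
      it <- it + 1L
      g_new <- if (loc_degenerate[bi] || !is.finite(tau2[bi])) gamma_hat[bi, ]
      else (n_i * tau2[bi] * gamma_hat[bi, ] + d_old * gamma_bar[bi]) /
        (n_i * tau2[bi] + d_old)
      sum2 <- rowSums((Zi - g_new)^2)
      d_new <- if (scale_degenerate[bi] &&
                   is.null(prior_overrides[["lambda"]])) delta2_hat[bi, ]
      else (theta[bi] + 0.5 * sum2) / (n_i / 2 + lambda[bi] - 1)
      change <- max(abs(g_new - g_old), abs(d_new - d_old))
      trace <- c(trace, change)
      g_old <- g_new
      d_old <- d_new
      if (change < tol) break
      if (it >= max_iter)
        stop(sprintf("EB fixed point did not converge in %d iterations (batch %d, residual change %.3g)",
                     max_iter, batches[bi], change))
    }
    gamma_star[bi, ] <- g_old
    delta2_star[bi, ] <- d_old
    iterations[bi] <- it
    residual_trace[[bi]] <- trace
    Zc[, in_b] <- (Zi - g_old) / sqrt(d_old)
  }
  list(Z_corrected = Zc, gamma_hat = gamma_hat, delta2_hat = delta2_hat,
       gamma_star = gamma_star, delta2_star = delta2_star,
       hyper = list(gamma_bar = gamma_bar, tau2 = tau2,
                    lambda = lambda, theta = theta),
       iterations = iterations, residual_trace = residual_trace)
}

#' Remove batch effects from an expression matrix
#'
#' Composition of [build_design()], [standardize_expression()],
#' [eb_adjust()] and de-standardization: corrected values are
#' \eqn{Y^* = \sigma_g (Z - \gamma^*)/\delta^* + \alpha_g + X\beta_g}.
#' Invariant genes pass through bit-identical.
#'
#' @param m an [expr_matrix()], typically log2-transformed.
#' @param batch integer batch labels (1..B), one per sample.
#' @param covariates optional data.frame of biological covariates to
#'   preserve (e.g. species, tissue).
#' @param tol,max_iter passed to [eb_adjust()].
#' @return the corrected [expr_matrix()], with the fitted `batch_model`
#'   attached as an attribute and a provenance record.
#' @export
combat_correct <- function(m, batch, covariates = NULL, tol = 1e-4,
                           max_iter = 500L) {
  stopifnot(inherits(m, "expr_matrix"))
  design <- build_design(batch, covariates)
  std <- standardize_expression(m, design)
  ok <- !std$invariant
  eb <- eb_adjust(std$Z[ok, , drop = FALSE], batch, tol = tol,
                  max_iter = max_iter)
  out <- m$values
  if (design$n_batches == 1L) {
    # one batch: there is no batch effect to remove, and the n_i - 1
    # convention of the scale estimates must not rescale the data
    eb$Z_corrected <- std$Z[ok, , drop = FALSE]
  }
  out[ok, ] <- std$sigma[ok] * eb$Z_corrected +
    std$alpha[ok] + std$cov_part[ok, , drop = FALSE]
  model <- list(design = design, alpha = std$alpha, beta = std$beta,
                sigma = std$sigma, invariant = std$invariant, eb = eb)
  res <- em_update(m, values = out, step = "combat_correct",
                   params = list(n_batches = design$n_batches,
                                 covariates = if (is.null(covariates)) ""
                                 else paste(colnames(as.data.frame(covariates)),
                                            collapse = ","),
                                 iterations = max(eb$iterations)))
  attr(res, "batch_model") <- model
  res
}
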