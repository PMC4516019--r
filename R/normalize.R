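#' Remove the lowest-expressed fraction of genes
#'
#' Genes are ranked by their total fragment count across all samples and the
#' lowest `floor(fraction * n_genes)` are removed; ties are broken by
#' original row order (stable sort), and surviving genes keep their original
#' order. With 14,744 genes and the default fraction, 4,423 genes go and
#' 10,321 remain.
#'
#' @param m an [expr_matrix()] of raw counts.
#' @param fraction fraction of genes to drop, in `[0, 1)`.
#' @return list with `kept` (the filtered [expr_matrix()]) and `removed`
#'   (gene names, in removal-rank order).
#' @export
filter_low_expression <- function(m, fraction = 0.3) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$value_kind != "raw_count")
    stop("low-expression filter is defined on raw counts, got ", m$value_kind)
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(m$values)
  n_drop <- floor(fraction * n)
  totals <- rowSums(m$values)
  o <- order(totals)                    # stable: ties keep original order
  drop_idx <- sort(o[seq_len(n_drop)])
  keep_idx <- setdiff(seq_len(n), drop_idx)
  list(kept = em_update(m, values = m$values[keep_idx, , drop = FALSE],
                        gene_names = m$gene_names[keep_idx],
                        step = "filter_low_expression",
                        params = list(fraction = fraction, n_removed = n_drop)),
       removed = m$gene_names[o[seq_len(n_drop)]])
}

#' Remove named genes (e.g. the mitochondrial genes)
#'
#' @param m an [expr_matrix()].
#' @param names gene names to remove; names not present are warned about.
#' @return list with `kept` and `removed` as in [filter_low_expression()].
#' @export
remove_genes <- function(m, names) {
  stopifnot(inherits(m, "expr_matrix"))
  present <- names %in% m$gene_names
  if (any(!present))
    warning("gene(s) not present (already filtered?): ",
            paste(names[!present], collapse = ", "))
  keep <- !(m$gene_names %in% names)
  list(kept = em_update(m, values = m$values[keep, , drop = FALSE],
                        gene_names = m$gene_names[keep],
                        step = "remove_genes",
                        params = list(n_removed = sum(!keep))),
       removed = m$gene_names[!keep])
}

#' Within-sample GC-content normalization
#'
#' Removes the dependence of a sample's counts on gene GC content,
#' column by column. Genes are stratified into `num_bins` equal-occupancy GC
#' bins and one of three adjustments is applied per column:
#'
#' * `full_quantile` (default): counts in each bin are quantile-matched to
#'   the column's pooled count distribution — each value is replaced by the
#'   pooled quantile at its within-bin rank (average ranks at ties). Rank
#'   order within a bin is preserved; deterministic.
#' * `median`: each bin's nonzero median is scaled to the column's global
#'   nonzero median.
#' * `loess`: a smooth regression of `log(count + 0.5)` on GC is subtracted
#'   and recentered.
#'
#' Output is rounded to the nearest integer and floored at 0, keeping the
#' matrix count-like.
#'
#' @param m an [expr_matrix()] of raw counts.
#' @param gc named numeric vector of per-gene GC fractions (names matching
#'   `m$gene_names`), or a GC table data.frame with `common_name` and
#'   `gc_fraction` columns.
#' @param method one of `"full_quantile"`, `"median"`, `"loess"`.
#' @param num_bins number of GC strata (>= 2).
#' @return the normalized [expr_matrix()] (`value_kind = "gc_normalized"`).
#' @export
gc_normalize_within_sample <- function(m, gc,
                                       method = c("full_quantile", "median",
                                                  "loess"),
                                       num_bins = 10L) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  if (num_bins < 2L) stop("num_bins must be >= 2")
  if (is.data.frame(gc))
    gc <- stats::setNames(gc$gc_fraction, gc$common_name)
  gcv <- gc[m$gene_names]
  if (anyNA(gcv))
    stop("genes lacking a GC value: ",
         paste(utils::head(m$gene_names[is.na(gcv)], 10), collapse = ", "))
  n <- length(gcv)
  # equal-occupancy bins by GC rank
  bin <- ceiling(rank(gcv, ties.method = "first") * num_bins / n)
  out <- m$values
  for (j in seq_len(ncol(out))) {
    x <- m$values[, j]
    if (method == "full_quantile") {
      pooled <- sort(x)
      for (b in seq_len(num_bins)) {
        idx <- which(bin == b)
        v <- x[idx]
        r <- rank(v, ties.method = "average")
        p <- (r - 0.5) / length(v)
        out[idx, j] <- stats::quantile(pooled, probs = p, names = FALSE,
                                       type = 7)
      }
    } else if (method == "median") {
      gmed <- stats::median(x[x > 0])
      for (b in seq_len(num_bins)) {
        idx <- which(bin == b)
        v <- x[idx]
        bmed <- stats::median(v[v > 0])
        if (is.finite(bmed) && bmed > 0)
          out[idx, j] <- v * gmed / bmed
      }
    } else {
      lx <- log(x + 0.5)
      fit <- stats::loess(lx ~ gcv, degree = 2, span = 0.75)
      out[, j] <- exp(lx - stats::fitted(fit) + mean(stats::fitted(fit))) - 0.5
    }
  }
  out <- pmax(round(out), 0)
  em_update(m, values = out, value_kind = "gc_normalized",
            step = "gc_normalize_within_sample",
            params = list(method = method, num_bins = num_bins))
}

#' Correlation between GC-stratum mean expression and stratum GC
#'
#' The bias diagnostic paired with [gc_normalize_within_sample()]: genes are
#' stratified into `num_bins` equal-occupancy GC bins and the Pearson
#' correlation between per-bin mean value and per-bin mean GC is returned.
#' A well-normalized column has bin means that are constant up to numerical
#' dust; correlation is scale-free, so it would amplify that dust into an
#' arbitrary number. Below a relative bin-mean spread of `floor` (0.5% by
#' default, orders of magnitude under any real bias) the association is
#' reported as 0.
#'
#' @param x numeric vector of one column's values.
#' @param gc per-gene GC fractions, same length/order.
#' @param num_bins GC strata.
#' @param floor relative bin-mean spread under which the correlation is 0.
#' @return a single correlation in `[-1, 1]`.
#' @export
gc_bias_correlation <- function(x, gc, num_bins = 10L, floor = 5e-3) {
  bin <- ceiling(rank(gc, ties.method = "first") * num_bins / length(gc))
  bm <- tapply(x, bin, mean)
  bg <- tapply(gc, bin, mean)
  if (diff(range(bm)) < floor * abs(mean(bm))) return(0)
  stats::cor(bm, bg)
}

#' Trimmed-mean-of-M-values (TMM) composition normalization factors
#'
#' For each sample \eqn{k} against a reference sample \eqn{r}, over genes
#' positive in both, compute the log-ratio
#' \eqn{M_g = \log_2((y_{gk}/N_k)/(y_{gr}/N_r))} and average log-abundance
#' \eqn{A_g = \tfrac12 \log_2((y_{gk}/N_k)(y_{gr}/N_r))} with \eqn{N} the
#' column sums. Genes in the top/bottom 30% of M or top/bottom 5% of A are
#' discarded (double trimming), and the factor is
#' \eqn{2^{\sum w_g M_g / \sum w_g}} with inverse-variance (delta-method)
#' weights \eqn{w_g = [(N_k-y_{gk})/(N_k y_{gk}) + (N_r-y_{gr})/(N_r y_{gr})]^{-1}}.
#' The reference is the sample whose 75th percentile of scaled counts is
#' closest to the mean such percentile; factors are rescaled to geometric
#' mean 1.
#'
#' @param m an [expr_matrix()] of (possibly GC-normalized) counts with at
#'   least 2 samples.
#' @param logratio_trim,abundance_trim trim fractions for M and A.
#' @return list with `reference_sample`, `tmm_factor` (named, geometric mean
#'   1) and `effective_library_size` (`library_size_proxy * tmm_factor`;
#'   falls back to the matrix's own column sums, with a note in the result,
#'   when no proxy is carried).
#' @export
tmm_factors <- function(m, logratio_trim = 0.30, abundance_trim = 0.05) {
  stopifnot(inherits(m, "expr_matrix"))
  y <- m$values
  if (ncol(y) < 2L) stop("TMM needs at least 2 samples")
  N <- colSums(y)
  if (any(N == 0)) stop("all-zero column(s): ",
                        paste(m$sample_ids[N == 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(y)),
                function(j) stats::quantile(y[, j] / N[j], 0.75, names = FALSE),
                0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- numeric(ncol(y))
  for (k in seq_len(ncol(y))) {
    if (k == ref) { f[k] <- 1; next }
    pos <- y[, k] > 0 & y[, ref] > 0
    yk <- y[pos, k]; yr <- y[pos, ref]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (sum(keep) < 10L) {
      warning("fewer than 10 genes survive TMM trimming for sample ",
              m$sample_ids[k], "; factor set to 1")
      f[k] <- 1
      next
    }
    w <- 1 / ((N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr))
    f[k] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- f / exp(mean(log(f)))
  names(f) <- m$sample_ids
  lsp <- m$library_size_proxy
  proxy_source <- "library_size_proxy"
  if (is.null(lsp)) {
    lsp <- stats::setNames(N, m$sample_ids)
    proxy_source <- "matrix_column_sums"
  }
  list(reference_sample = m$sample_ids[ref],
       tmm_factor = f,
       effective_library_size = lsp * f,
       proxy_source = proxy_source)
}

#' Depth-normalize columns by effective library size
#'
#' Each column is divided by its effective library size (library-size proxy
#' times TMM factor) and rescaled by the mean effective size, keeping
#' magnitudes count-like. All downstream summaries (correlations,
#' standardized PCA) are invariant to that global scale; `per_million = TRUE`
#' rescales to counts-per-million instead.
#'
#' @param m an [expr_matrix()].
#' @param factors result of [tmm_factors()].
#' @param per_million rescale by 1e6 instead of the mean effective size.
#' @return the depth-normalized [expr_matrix()].
#' @export
depth_normalize <- function(m, factors, per_million = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  eff <- factors$effective_library_size[m$sample_ids]
  if (anyNA(eff)) stop("effective library size missing for some samples")
  if (any(eff <= 0)) stop("non-positive effective library size")
  scale_to <- if (per_million) 1e6 else mean(eff)
  out <- sweep(m$values, 2L, eff, "/") * scale_to
  em_update(m, values = out, value_kind = "depth_normalized",
            step = "depth_normalize",
            params = list(scale = if (per_million) "per_million" else
              "mean_effective_size"))
}

#' log2(x + pseudocount) transform
#'
#' @param m an [expr_matrix()] with non-negative values.
#' @param pseudocount added before taking logs to avoid log2(0).
#' @return the transformed [expr_matrix()] (`value_kind = "log2"`).
#' @export
log_transform <- function(m, pseudocount = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (any(m$values < 0)) stop("negative values cannot be log-transformed")
  em_update(m, values = log2(m$values + pseudocount), value_kind = "log2",
            step = "log_transform", params = list(pseudocount = pseudocount))
}
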