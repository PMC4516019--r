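#' PCA of samples over genes
#'
#' Samples are the observations (the matrix is transposed internally), genes
#' the variables; invariant genes (sample variance exactly 0) are removed
#' first. Computed via [stats::prcomp] with centering and scaling on by
#' default. Component signs are fixed so that each loading vector's
#' largest-magnitude entry is positive, making plots reproducible.
#'
#' @param m an [expr_matrix()], typically log2 values.
#' @param center,scale passed to [stats::prcomp].
#' @return list with `scores` (samples x components), `loadings` (genes x
#'   components), `variance_fraction` (sums to 1 over computed components)
#'   and `dropped_invariant_genes`.
#' @export
pca_samples <- function(m, center = TRUE, scale = TRUE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2L) stop("PCA needs at least 2 samples")
  vars <- apply(m$values, 1L, stats::var)
  invariant <- vars == 0
  X <- t(m$values[!invariant, , drop = FALSE])
  p <- stats::prcomp(X, center = center, scale. = scale)
  flip <- apply(p$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2L, flip, "*")
  loadings <- sweep(p$rotation, 2L, flip, "*")
  list(scores = scores,
       loadings = loadings,
       variance_fraction = p$sdev^2 / sum(p$sdev^2),
       dropped_invariant_genes = m$gene_names[invariant])
}

#' Sample-sample correlation matrix
#'
#' @param m an [expr_matrix()].
#' @param method `"pearson"` or `"spearman"` (Pearson on within-column
#'   average ranks).
#' @return samples x samples correlation matrix; zero-variance samples get
#'   `NA` correlations and are listed in the `flagged` attribute.
#' @export
correlation_matrix <- function(m, method = c("pearson", "spearman")) {
  stopifnot(inherits(m, "expr_matrix"))
  method <- match.arg(method)
  if (nrow(m$values) < 2L) stop("need at least 2 genes")
  zero_var <- apply(m$values, 2L, stats::var) == 0
  C <- suppressWarnings(stats::cor(m$values, method = method))
  diag(C) <- 1
  if (any(zero_var)) {
    C[zero_var, ] <- NA_real_
    C[, zero_var] <- NA_real_
    diag(C) <- 1
  }
  attr(C, "flagged") <- m$sample_ids[zero_var]
  C
}

#' Hierarchical clustering of samples with a deterministic tie-break
#'
#' Agglomerative clustering over one of three distance sources:
#' `corr_rows_euclidean` (the heatmap default — Euclidean distance between
#' rows of the sample correlation matrix, which is what a heatmap tool does
#' when handed a correlation matrix as data), `one_minus_corr`, or
#' `data_euclidean` (Euclidean distance between sample columns of the data
#' itself). Linkage is complete, average (UPGMA), or Ward (on squared
#' distances, square-root heights). Ties are broken by merging the
#' lexicographically smallest pair of cluster indices, so trees are
#' reproducible bit-for-bit.
#'
#' @param m an [expr_matrix()].
#' @param dist_source one of `"corr_rows_euclidean"`, `"one_minus_corr"`,
#'   `"data_euclidean"`.
#' @param linkage `"complete"`, `"average"` or `"ward"`.
#' @param corr_method correlation flavor for the correlation-based sources.
#' @return list with `correlation` (or `NULL` for `data_euclidean`),
#'   `distance` (matrix), `tree` (an object of class `hclust`),
#'   `dist_source`, `linkage`.
#' @export
hcluster_samples <- function(m,
                             dist_source = c("corr_rows_euclidean",
                                             "one_minus_corr",
                                             "data_euclidean"),
                             linkage = c("complete", "average", "ward"),
                             corr_method = "pearson") {
  stopifnot(inherits(m, "expr_matrix"))
  dist_source <- match.arg(dist_source)
  linkage <- match.arg(linkage)
  C <- NULL
  if (dist_source == "corr_rows_euclidean") {
    C <- correlation_matrix(m, corr_method)
    D <- as.matrix(stats::dist(C))
  } else if (dist_source == "one_minus_corr") {
    C <- correlation_matrix(m, corr_method)
    D <- 1 - C
  } else {
    D <- as.matrix(stats::dist(t(m$values)))
  }
  if (any(!is.finite(D))) stop("non-finite distances")
  tree <- if (linkage == "ward") agglomerate_ward(D, labels = m$sample_ids)
  else agglomerate(D, linkage, labels = m$sample_ids)
  list(correlation = C, distance = D, tree = tree,
       dist_source = dist_source, linkage = linkage)
}

# Naive O(n^3) agglomeration with the lexicographic tie rule; returns a
# stats::hclust-compatible object so cutree/dendrogram machinery applies.
agglomerate <- function(D, linkage, labels = NULL) {
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 objects")
  d <- D
  diag(d) <- Inf
  active <- seq_len(n)            # position -> TRUE while clusterable
  alive <- rep(TRUE, n)
  sizes <- rep(1L, n)
  node <- -seq_len(n)             # hclust convention: -i singleton, +k merge k
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    idx <- which(alive)
    for (a in seq_along(idx)) {
      i <- idx[a]
      if (a == length(idx)) break
      for (j in idx[(a + 1L):length(idx)]) {
        if (d[i, j] < best) { best <- d[i, j]; bi <- i; bj <- j }
      }
    }
    pair <- sort(node[c(bi, bj)])
    # hclust merge rows list singletons (negative) before clusters, and
    # within a type smaller first; sort() on the signed codes gives exactly
    # the conventional order
    merge[s, ] <- pair
    height[s] <- if (linkage == "ward") sqrt(best) else best
    ni <- sizes[bi]; nj <- sizes[bj]
    for (k in which(alive)) {
      if (k == bi || k == bj) next
      d[bi, k] <- d[k, bi] <- switch(
        linkage,
        complete = max(d[bi, k], d[bj, k]),
        average = (ni * d[bi, k] + nj * d[bj, k]) / (ni + nj),
        ward = {
          nk <- sizes[k]
          ((ni + nk) * d[bi, k] + (nj + nk) * d[bj, k] - nk * best) /
            (ni + nj + nk)
        })
    }
    alive[bj] <- FALSE
    sizes[bi] <- ni + nj
    node[bi] <- s
  }
  order <- tree_leaf_order(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, method = linkage,
                 call = match.call(), dist.method = "precomputed"),
            class = "hclust")
}

# For ward the Lance-Williams recursion above operates on squared
# distances; feed it squares and report sqrt heights.
agglomerate_ward <- function(D, labels = NULL) {
  agglomerate(D^2, "ward", labels)
}

tree_leaf_order <- function(merge) {
  rec <- function(k) {
    if (k < 0) return(-k)
    c(rec(merge[k, 1]), rec(merge[k, 2]))
  }
  rec(nrow(merge))
}

#' Cut a clustering into k groups
#'
#' @param cl result of [hcluster_samples()].
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_clusters <- function(cl, k) {
  stats::cutree(cl$tree, k = k)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' about 0 for unrelated ones.
#'
#' @param a,b partition label vectors over the same samples.
#' @return a single number.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partition length mismatch")
  if (length(a) < 2L) stop("need at least 2 samples")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Nearest-neighbor label purity
#'
#' Fraction of samples whose most-correlated other sample carries the same
#' label.
#'
#' @param correlation samples x samples correlation matrix.
#' @param labels label vector (in the correlation matrix's sample order).
#' @return a single number in `[0, 1]`.
#' @export
nn_purity <- function(correlation, labels) {
  n <- nrow(correlation)
  if (n < 2L) stop("need at least 2 samples")
  if (length(labels) != n) stop("labels/correlation mismatch")
  hits <- vapply(seq_len(n), function(i) {
    cc <- correlation[i, ]
    cc[i] <- -Inf
    labels[which.max(cc)] == labels[i]
  }, logical(1))
  mean(hits)
}

#' Partition/label agreement summary
#'
#' @param partition cluster membership vector (e.g. from [cut_clusters()]).
#' @param labels reference label vector (tissue or species).
#' @param correlation optional correlation matrix for nearest-neighbor
#'   purity; `NA` returned when absent.
#' @return list with `ari` and `nn_purity`.
#' @export
label_agreement <- function(partition, labels, correlation = NULL) {
  list(ari = adjusted_rand_index(partition, labels),
       nn_purity = if (is.null(correlation)) NA_real_
       else nn_purity(correlation, labels))
}
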