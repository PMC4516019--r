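# Independent oracles, deliberately loop-based / brute-force so they share
# no code path with the package implementations they check.

# TMM factors, step by step with explicit per-gene loops
oracle_tmm <- function(y, logratio_trim = 0.3, abundance_trim = 0.05) {
  N <- colSums(y)
  f75 <- sapply(seq_len(ncol(y)),
                function(j) quantile(y[, j] / N[j], 0.75, names = FALSE))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- rep(NA_real_, ncol(y))
  for (k in seq_len(ncol(y))) {
    if (k == ref) { f[k] <- 1; next }
    M <- A <- w <- c()
    for (g in seq_len(nrow(y))) {
      if (y[g, k] > 0 && y[g, ref] > 0) {
        pk <- y[g, k] / N[k]; pr <- y[g, ref] / N[ref]
        M <- c(M, log2(pk / pr))
        A <- c(A, 0.5 * log2(pk * pr))
        w <- c(w, 1 / ((N[k] - y[g, k]) / (N[k] * y[g, k]) +
                         (N[ref] - y[g, ref]) / (N[ref] * y[g, ref])))
      }
    }
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[k] <- 2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f / exp(mean(log(f)))
}

# adjusted Rand index from explicit pair counting (not the contingency form)
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(0)
  2 * (n11 * n00 - n10 * n01) / denom
}

# per-base boolean-mask union of intervals on one chromosome
oracle_union_length <- function(starts, ends) {
  mask <- rep(FALSE, max(ends))
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  sum(mask)
}

# GC of given 1-based inclusive intervals on a chromosome string, counting
# character by character
oracle_gc <- function(seq_string, starts, ends) {
  mask <- rep(FALSE, nchar(seq_string))
  for (i in seq_along(starts)) mask[starts[i]:ends[i]] <- TRUE
  chars <- toupper(strsplit(seq_string, "")[[1]][mask])
  gc <- sum(chars %in% c("G", "C"))
  acgt <- sum(chars %in% c("A", "C", "G", "T"))
  list(gc_fraction = if (acgt > 0) gc / acgt else NA_real_,
       unambiguous_length = acgt)
}

# random valid identifier lines for round-trip property tests
random_token <- function(len = 8) {
  paste(sample(c(LETTERS, 0:9), len, replace = TRUE), collapse = "")
}
random_v18_line <- function() {
  sprintf("@%s:%d:%s:%d:%d:%d:%d %d:%s:%d:%s",
          random_token(), sample(0:999, 1), random_token(9),
          sample(1:8, 1), sample(1101:2316, 1), sample(0:30000, 1),
          sample(0:200000, 1), sample(1:2, 1), sample(c("Y", "N"), 1),
          sample(c(0L, 18L), 1),
          paste(sample(c("A", "C", "G", "T", "N"), 6, TRUE), collapse = ""))
}
random_pre18_line <- function() {
  sprintf("@%s:%d:%d:%d:%d#%s/%d",
          random_token(), sample(1:8, 1), sample(1:120, 1),
          sample(0:30000, 1), sample(0:200000, 1),
          sample(c("0", "ACGTAC", "12"), 1), sample(1:2, 1))
}

# small metadata table + identifier lines realizing the default layout
figure1_samples <- function(seed = 1L) {
  set.seed(seed)
  lay <- figure1_layout()
  lay$identifier_line <- simulate_fastq_headers(lay)
  lay
}
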