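#' Expression matrix container
#'
#' A light S3 container for a genes x samples expression grid, tagged with
#' the kind of value it holds and carrying per-sample library-size proxies
#' (the column sums of the original, unfiltered count matrix) through every
#' later transformation.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param gene_names character vector, one per row.
#' @param sample_ids character vector, one per column.
#' @param value_kind one of `"raw_count"`, `"fpkm"`, `"gc_normalized"`,
#'   `"depth_normalized"`, `"log2"`.
#' @param library_size_proxy named numeric vector (names = sample ids), or
#'   `NULL` if not yet set. Once set it is treated as immutable: downstream
#'   steps copy it, never recompute it.
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_names, sample_ids,
                        value_kind = c("raw_count", "fpkm", "gc_normalized",
                                       "depth_normalized", "log2"),
                        library_size_proxy = NULL) {
  value_kind <- match.arg(value_kind)
  values <- as.matrix(values)
  if (nrow(values) != length(gene_names))
    stop("nrow(values) != length(gene_names)")
  if (ncol(values) != length(sample_ids))
    stop("ncol(values) != length(sample_ids)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  dimnames(values) <- list(gene_names, sample_ids)
  if (!is.null(library_size_proxy)) {
    if (is.null(names(library_size_proxy)))
      names(library_size_proxy) <- sample_ids
    if (!all(sample_ids %in% names(library_size_proxy)))
      stop("library_size_proxy must cover every sample id")
    library_size_proxy <- library_size_proxy[sample_ids]
  }
  structure(
    list(values = values,
         gene_names = as.character(gene_names),
         sample_ids = as.character(sample_ids),
         value_kind = value_kind,
         library_size_proxy = library_size_proxy,
         provenance = list()),
    class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$value_kind))
  if (!is.null(x$library_size_proxy))
    cat(sprintf("  library-size proxy: %s..\n",
                paste(signif(utils::head(x$library_size_proxy, 3), 4),
                      collapse = ", ")))
  if (length(x$provenance))
    cat("  provenance:", paste(vapply(x$provenance, `[[`, "", "step"),
                               collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# internal: derive a modified copy, appending a provenance record
em_update <- function(m, values = m$values, gene_names = m$gene_names,
                      value_kind = m$value_kind, step = NULL, params = list()) {
  out <- m
  out$values <- as.matrix(values)
  out$gene_names <- as.character(gene_names)
  dimnames(out$values) <- list(out$gene_names, out$sample_ids)
  out$value_kind <- value_kind
  if (!is.null(step))
    out$provenance <- c(m$provenance, list(c(list(step = step), params)))
  out
}

#' Write / read an expression matrix as TSV plus a JSON sidecar
#'
#' The TSV has a `gene` column followed by one column per sample; the sidecar
#' (same path with `.json` appended) records `value_kind`, the library-size
#' proxies and the provenance chain.
#'
#' @param m an [expr_matrix()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(m, path) {
  df <- data.frame(gene = m$gene_names, m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(value_kind = m$value_kind,
                  library_size_proxy = as.list(m$library_size_proxy),
                  provenance = m$provenance)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
read_expr_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE) else list()
  lsp <- sidecar$library_size_proxy
  if (!is.null(lsp)) lsp <- unlist(lsp)
  m <- expr_matrix(as.matrix(df[, -1, drop = FALSE]),
                   gene_names = df$gene,
                   sample_ids = colnames(df)[-1],
                   value_kind = if (!is.null(sidecar$value_kind))
                     sidecar$value_kind else "raw_count",
                   library_size_proxy = lsp)
  if (!is.null(sidecar$provenance)) {
    prov <- sidecar$provenance
    m$provenance <- if (is.data.frame(prov))
      lapply(seq_len(nrow(prov)), function(i) as.list(prov[i, ]))
    else as.list(prov)
  }
  m
}
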