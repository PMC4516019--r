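#' Resolve quantifier gene identifiers to common names
#'
#' Quantifier output identifies genes by stable identifiers (ENSEMBL-style);
#' the ortholog table uses common names. The GC table carries both and
#' drives the mapping. Identifiers retired from the database but retained in
#' the GTF are dropped outright; when several surviving identifiers share a
#' common name, the first appearance in the GC table wins.
#'
#' @param quant data.frame with columns `gene_id`, `value` (one sample).
#' @param gc_table data.frame with `gene_id`, `common_name` (see
#'   [build_gc_table()]); its row order defines "first appearance".
#' @param retired_ids character vector of retired identifiers to ignore.
#' @return named numeric vector (names = common names), with attributes
#'   `n_retired_dropped`, `n_unknown_dropped`, `n_name_collisions`.
#' @export
resolve_gene_ids <- function(quant, gc_table, retired_ids = character()) {
  stopifnot(all(c("gene_id", "value") %in% names(quant)))
  retired <- quant$gene_id %in% retired_ids
  q <- quant[!retired, , drop = FALSE]
  pos <- match(q$gene_id, gc_table$gene_id)
  unknown <- is.na(pos)
  if (any(unknown))
    warning(sum(unknown), " gene_id(s) absent from GC table; dropped")
  q <- q[!unknown, , drop = FALSE]
  pos <- pos[!unknown]
  # order by gc-table position so "first appearance of the common name" wins
  o <- order(pos)
  q <- q[o, , drop = FALSE]
  nm <- gc_table$common_name[pos[o]]
  dup <- duplicated(nm)
  out <- q$value[!dup]
  names(out) <- nm[!dup]
  attr(out, "n_retired_dropped") <- sum(retired)
  attr(out, "n_unknown_dropped") <- sum(unknown)
  attr(out, "n_name_collisions") <- sum(dup)
  out
}

#' Assemble the ortholog expression matrix from per-sample quantifications
#'
#' Rows follow the ortholog table's order; a pair's row takes the human
#' gene's value in human columns and the mouse gene's value in mouse
#' columns. Genes missing from a sample's quantification are filled with 0
#' (quantifiers emit zero rows for unexpressed genes, so absence usually
#' means identifier-version drift) and counted in a warning.
#'
#' @param quants named list of data.frames (`gene_id`, `value`), one per
#'   sample; names are sample ids.
#' @param metadata data.frame with `sample_id`, `species` (`"human"` /
#'   `"mouse"`); column order of the matrix follows this table.
#' @param orthologs an `ortholog_table` (columns `human`, `mouse`).
#' @param human_gc,mouse_gc GC tables for the two species.
#' @param retired_human,retired_mouse retired identifier sets.
#' @param value_kind `"raw_count"` or `"fpkm"`.
#' @param full_column_sums optional named numeric vector of library-size
#'   proxies (column sums of the quantifier's *full* output, before ortholog
#'   subsetting). When absent and `value_kind = "raw_count"`, each sample's
#'   full quant-table sum is used.
#' @return an [expr_matrix()] of dimension `nrow(orthologs)` x
#'   `nrow(metadata)`, rows named by human gene name.
#' @export
assemble_matrix <- function(quants, metadata, orthologs, human_gc, mouse_gc,
                            retired_human = character(),
                            retired_mouse = character(),
                            value_kind = c("raw_count", "fpkm"),
                            full_column_sums = NULL) {
  value_kind <- match.arg(value_kind)
  stopifnot(all(c("sample_id", "species") %in% names(metadata)))
  if (anyDuplicated(metadata$sample_id)) stop("duplicate sample_id")
  missing_q <- setdiff(metadata$sample_id, names(quants))
  if (length(missing_q))
    stop("no quantification for sample(s): ", paste(missing_q, collapse = ", "))

  n_g <- nrow(orthologs)
  vals <- matrix(0, nrow = n_g, ncol = nrow(metadata))
  lsp <- numeric(nrow(metadata))
  n_missing <- 0L
  for (j in seq_len(nrow(metadata))) {
    sid <- metadata$sample_id[j]
    sp <- metadata$species[j]
    quant <- quants[[sid]]
    resolved <- if (sp == "human")
      resolve_gene_ids(quant, human_gc, retired_human)
    else
      resolve_gene_ids(quant, mouse_gc, retired_mouse)
    want <- if (sp == "human") orthologs$human else orthologs$mouse
    hit <- match(want, names(resolved))
    n_missing <- n_missing + sum(is.na(hit))
    vals[, j] <- ifelse(is.na(hit), 0, resolved[hit])
    lsp[j] <- if (!is.null(full_column_sums)) {
      if (!sid %in% names(full_column_sums))
        stop("full_column_sums lacks sample ", sid)
      full_column_sums[[sid]]
    } else sum(quant$value)
  }
  if (n_missing > 0L)
    warning(n_missing, " ortholog gene/sample cell(s) missing from ",
            "quantifications; filled with 0")
  m <- expr_matrix(vals,
                   gene_names = orthologs$human,
                   sample_ids = metadata$sample_id,
                   value_kind = value_kind,
                   library_size_proxy = stats::setNames(lsp, metadata$sample_id))
  m$provenance <- list(list(
    step = "assemble_matrix",
    n_orthologs = n_g,
    library_size_source = if (!is.null(full_column_sums))
      "full_quantifier_output" else "quant_table_sums",
    n_missing_cells = n_missing))
  m
}

#' Read a featureCounts-style quantification table
#'
#' Expects a tab-delimited file whose first column is the gene identifier
#' and whose last column holds the counts (featureCounts layout; comment
#' lines starting with `#` skipped).
#'
#' @param path file path.
#' @return data.frame with columns `gene_id`, `value`.
#' @export
read_quant_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(gene_id = as.character(df[[1]]),
                    value = as.numeric(df[[ncol(df)]]),
                    stringsAsFactors = FALSE)
  if (any(out$value < 0)) stop("negative quantification values in ", path)
  out
}
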