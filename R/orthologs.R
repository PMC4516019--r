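#' Parse a modENCODE-style ortholog table
#'
#' Each record (line) of the ortholog file lists the member genes of an
#' orthology group and ends with two count columns: the number of human
#' genes in the group (second-to-last column) and the number of mouse genes
#' (last column). One-to-one human-mouse pairs are the records where both
#' counts are 1.
#'
#' A historically relevant subtlety: selecting one-to-one pairs with a text
#' search that only requires the *last* column to *begin* with "1" (rather
#' than equal "1" exactly) silently admits 1-to-10, 1-to-12, ... groups.
#' Both behaviors are implemented (`mode = "strict"` vs `mode = "prefix"`)
#' so the consequences of the lax match can be measured.
#'
#' @param path path to a whitespace-delimited ortholog file, plain or
#'   gzipped. Fields are split on runs of whitespace. The first field is the
#'   comma-separated human gene list, the second the mouse gene list
#'   (optional `species:` prefixes on names are stripped); any intervening
#'   fields (other species) are ignored; the last two fields are the counts,
#'   kept as raw strings.
#' @return list of `ortholog_record` lists with fields `human_genes`,
#'   `mouse_genes`, `n_human`, `n_mouse`, `raw_last_two`.
#' @export
read_ortholog_records <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  lapply(lines, function(ln) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(f) < 4L)
      stop("ortholog record with fewer than 4 fields: ", ln)
    nf <- length(f)
    raw_last_two <- f[c(nf - 1L, nf)]
    strip <- function(x) sub("^[A-Za-z]+:", "", strsplit(x, ",")[[1]])
    rec <- list(human_genes = strip(f[1]),
                mouse_genes = strip(f[2]),
                n_human = suppressWarnings(as.integer(raw_last_two[1])),
                n_mouse = suppressWarnings(as.integer(raw_last_two[2])),
                raw_last_two = raw_last_two)
    if (!is.na(rec$n_human) && rec$n_human != length(rec$human_genes))
      message("ortholog record count/list mismatch (human): ", ln)
    rec
  })
}

#' Select one-to-one ortholog pairs under strict or prefix column matching
#'
#' @param records output of [read_ortholog_records()].
#' @param mode `"strict"` keeps records whose last two columns are exactly
#'   `"1"` and `"1"`; `"prefix"` requires the second-to-last to be exactly
#'   `"1"` but the last merely to *begin* with `"1"`, reproducing a lax
#'   command-line selection. In prefix mode a multi-gene group contributes
#'   its first-listed gene from each species (logged — such pairs are not
#'   one-to-one orthologs by construction).
#' @return An `ortholog_table`: data.frame with columns `human`, `mouse`
#'   (one-to-one after first-occurrence de-duplication), plus attributes
#'   `parse_mode` and `provenance` (counts at each step).
#' @export
select_one_to_one <- function(records, mode = c("strict", "prefix")) {
  mode <- match.arg(mode)
  if (length(records) == 0L) {
    warning("empty ortholog record list")
    return(ortholog_table_df(character(), character(), mode,
                             list(n_records = 0L, n_selected = 0L,
                                  n_deduplicated = 0L)))
  }
  keep <- vapply(records, function(r) {
    if (mode == "strict")
      identical(r$raw_last_two, c("1", "1"))
    else
      r$raw_last_two[1] == "1" && startsWith(r$raw_last_two[2], "1")
  }, logical(1))
  sel <- records[keep]
  human <- vapply(sel, function(r) r$human_genes[1], "")
  mouse <- vapply(sel, function(r) r$mouse_genes[1], "")
  n_multi <- sum(vapply(sel, function(r) length(r$mouse_genes) > 1L ||
                          length(r$human_genes) > 1L, logical(1)))
  if (n_multi > 0L)
    message(n_multi, " selected group(s) list >1 gene for a species; ",
            "first-listed gene used (prefix-mode artifact)")
  dup <- duplicated(human) | duplicated(mouse)
  if (any(dup))
    warning(sum(dup), " duplicate pair(s) after selection; first kept")
  ortholog_table_df(human[!dup], mouse[!dup], mode,
                    list(n_records = length(records),
                         n_selected = length(sel),
                         n_multi_gene_groups = n_multi,
                         n_deduplicated = sum(dup)))
}

ortholog_table_df <- function(human, mouse, mode, provenance) {
  df <- data.frame(human = human, mouse = mouse, stringsAsFactors = FALSE)
  attr(df, "parse_mode") <- mode
  attr(df, "provenance") <- provenance
  class(df) <- c("ortholog_table", "data.frame")
  df
}

#' Keep only pairs whose both members appear in the annotations
#'
#' @param table an `ortholog_table`.
#' @param human_names,mouse_names character vectors (or sets) of gene common
#'   names present in the human and mouse transcript annotation.
#' @return the filtered `ortholog_table`, provenance extended with the
#'   before/after counts.
#' @export
intersect_with_annotation <- function(table, human_names, mouse_names) {
  if (length(human_names) == 0L || length(mouse_names) == 0L)
    stop("empty annotation name set — wrong annotation input?")
  keep <- table$human %in% human_names & table$mouse %in% mouse_names
  prov <- attr(table, "provenance")
  prov$n_before_intersection <- nrow(table)
  prov$n_after_intersection <- sum(keep)
  ortholog_table_df(table$human[keep], table$mouse[keep],
                    attr(table, "parse_mode"), prov)
}
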