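#' Per-gene GC content over the union of a gene's exons
#'
#' For every gene the exons of all its transcripts are merged into a set of
#' disjoint intervals covering the same bases, and GC content is computed as
#' (#G + #C) / (#A + #C + #G + #T) over that union. Ambiguity codes (N, ...)
#' count in neither numerator nor denominator; soft-masked lowercase bases
#' count as their uppercase equivalents. Strand is irrelevant: G+C is closed
#' under complementation.
#'
#' @name annotation_gc
NULL

#' Merge the exon intervals of one gene into disjoint intervals
#'
#' Coordinates are 1-based inclusive (GTF convention). Overlapping and
#' book-ended (`end + 1 == start`) intervals merge; merging is done per
#' chromosome. The operation is idempotent and order-invariant.
#'
#' @param exons data.frame with columns `chrom`, `start`, `end` (all rows
#'   one gene).
#' @return data.frame `chrom`, `start`, `end`, sorted by (chrom, start),
#'   pairwise disjoint, covering exactly the same bases as the input.
#' @export
merge_exons <- function(exons) {
  stopifnot(all(c("chrom", "start", "end") %in% names(exons)))
  if (any(exons$start > exons$end))
    stop("interval with start > end")
  gr <- GenomicRanges::GRanges(
    seqnames = exons$chrom,
    ranges = IRanges::IRanges(start = exons$start, end = exons$end))
  red <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red),
             end = GenomicRanges::end(red),
             stringsAsFactors = FALSE)
}

#' GC fraction of a set of merged exon intervals
#'
#' @param merged data.frame `chrom`, `start`, `end` (disjoint; see
#'   [merge_exons()]).
#' @param genome a named [Biostrings::DNAStringSet] (names = chromosomes).
#' @return list with `gc_fraction` (NA when no unambiguous bases) and
#'   `unambiguous_length`.
#' @export
gene_gc <- function(merged, genome) {
  missing_chr <- setdiff(unique(merged$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) missing from FASTA: ",
         paste(missing_chr, collapse = ", "))
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_len(nrow(merged))) {
    seq <- Biostrings::subseq(genome[[merged$chrom[i]]],
                              start = merged$start[i], end = merged$end[i])
    lf <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(as.character(seq))),
                                      letters = c("A", "C", "G", "T"))
    counts <- counts + as.numeric(lf)
  }
  denom <- sum(counts)
  list(gc_fraction = if (denom > 0) (counts[["C"]] + counts[["G"]]) / denom
       else NA_real_,
       unambiguous_length = as.integer(denom))
}

#' Harmonize chromosome names between a GTF and a genome FASTA
#'
#' Applies an explicit rename map first, then an automatic "chr" prefix
#' add/strip pass toward the genome's naming.
#'
#' @param chroms character vector of chromosome names (from the GTF).
#' @param genome_names chromosome names present in the FASTA.
#' @param rename optional named character vector `old = new`.
#' @return character vector of harmonized names.
#' @export
harmonize_chrom_names <- function(chroms, genome_names, rename = NULL) {
  out <- chroms
  if (!is.null(rename)) {
    hit <- out %in% names(rename)
    out[hit] <- rename[out[hit]]
  }
  fix <- !(out %in% genome_names)
  if (any(fix)) {
    stripped <- sub("^chr", "", out[fix])
    added <- paste0("chr", out[fix])
    out[fix] <- ifelse(stripped %in% genome_names, stripped,
                       ifelse(added %in% genome_names, added, out[fix]))
  }
  out
}

#' Build the per-gene GC table from a GTF and a genome FASTA
#'
#' @param gtf path to a GTF with `exon` features carrying `gene_id` and
#'   `gene_name` attributes.
#' @param fasta path to the genome FASTA.
#' @param rename optional chromosome rename map (see
#'   [harmonize_chrom_names()]).
#' @return data.frame with columns `gene_id`, `common_name`, `gc_fraction`,
#'   `unambiguous_length`, one row per gene_id in order of first appearance
#'   in the GTF. Genes with zero unambiguous bases get `NA` GC and a
#'   warning.
#' @export
build_gc_table <- function(gtf, fasta, rename = NULL) {
  feats <- rtracklayer::import(gtf, format = "gtf")
  feats <- feats[feats$type == "exon"]
  if (length(feats) == 0L) stop("no exon features in GTF: ", gtf)
  gene_id <- feats$gene_id
  if (is.null(gene_id) || any(is.na(gene_id) | gene_id == ""))
    stop("exon feature lacking gene_id in GTF: ", gtf)
  common <- feats$gene_name
  if (is.null(common)) common <- gene_id
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  chrom <- harmonize_chrom_names(
    as.character(GenomicRanges::seqnames(feats)), names(genome), rename)

  ids <- unique(gene_id)
  name_of <- common[match(ids, gene_id)]
  out <- data.frame(gene_id = ids, common_name = name_of,
                    gc_fraction = NA_real_, unambiguous_length = 0L,
                    stringsAsFactors = FALSE)
  exon_df <- data.frame(chrom = chrom,
                        start = GenomicRanges::start(feats),
                        end = GenomicRanges::end(feats),
                        gene_id = gene_id, stringsAsFactors = FALSE)
  by_gene <- split(exon_df, factor(exon_df$gene_id, levels = ids))
  for (i in seq_along(ids)) {
    merged <- merge_exons(by_gene[[i]])
    gc <- gene_gc(merged, genome)
    out$gc_fraction[i] <- gc$gc_fraction
    out$unambiguous_length[i] <- gc$unambiguous_length
  }
  if (anyNA(out$gc_fraction))
    warning(sum(is.na(out$gc_fraction)),
            " gene(s) with zero unambiguous bases; GC reported as NA")
  out
}
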