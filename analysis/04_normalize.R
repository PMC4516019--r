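#!/usr/bin/env Rscript

# The preprocessing stack on raw fragment counts: drop the 30% of genes
# with the lowest total counts, remove the 12 mitochondrial genes, remove
# each sample's GC-content bias by full-quantile matching within GC strata,
# compute TMM composition factors, depth-normalize against the original
# unfiltered column sums, and log2(x + 1) transform.

suppressPackageStartupMessages(library(confoundr))

m <- read_expr_matrix("results/assembled_counts.tsv")
gc_tab <- read.delim("results/data/gc_human.tsv")
mito <- readLines("results/data/mito_genes.txt")

norm <- normalize_pipeline(m, gc_tab, mito_genes = mito)

cat(sprintf("%d genes -> %d after 30%% filter -> %d after removing %d mito\n",
            nrow(m$values),
            nrow(m$values) - length(norm$removed_low),
            nrow(norm$log2$values), length(norm$removed_mito)))

bias_before <- mean(abs(apply(norm$filtered$values, 2, gc_bias_correlation,
                              gc = setNames(gc_tab$gc_fraction,
                                            gc_tab$common_name)[norm$filtered$gene_names])))
bias_after <- mean(abs(apply(norm$gc_normalized$values, 2, gc_bias_correlation,
                             gc = setNames(gc_tab$gc_fraction,
                                           gc_tab$common_name)[norm$gc_normalized$gene_names])))
cat(sprintf("Mean |GC-stratum bias correlation|: %.3f before, %.3f after\n",
            bias_before, bias_after))
cat(sprintf("TMM factors: reference %s, range [%.3f, %.3f]\n",
            norm$factors$reference_sample,
            min(norm$factors$tmm_factor), max(norm$factors$tmm_factor)))

write_expr_matrix(norm$log2, "results/normalized_log2.tsv")
write.table(data.frame(sample_id = names(norm$factors$tmm_factor),
                       tmm_factor = norm$factors$tmm_factor,
                       effective_library_size =
                         norm$factors$effective_library_size),
            "results/tmm_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
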