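#!/usr/bin/env Rscript

# Generate the synthetic confounded study: 26 samples (13 tissues x human
# and mouse) sequenced in five batches, four of them species-pure, with
# batch effects (log2 sd 2.0) dominating tissue (1.0) and species (0.5)
# signal — the design whose consequences the rest of the analysis unpacks.
# Writes every input the downstream steps consume under results/data/.

suppressPackageStartupMessages(library(confoundr))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

cfg <- sim_config(seed = 1L)            # n_genes = 2000 at analysis scale
sim <- simulate_counts(cfg)

write.table(sim$metadata, file.path(out, "metadata.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_expr_matrix(sim$matrix, file.path(out, "counts.tsv"))
write.table(sim$gc_human, file.path(out, "gc_human.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sim$gc_mouse, file.path(out, "gc_mouse.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(sim$truth$mito_genes, file.path(out, "mito_genes.txt"))
writeLines(sim$truth$retired_human, file.path(out, "retired_human.txt"))
writeLines(sim$truth$retired_mouse, file.path(out, "retired_mouse.txt"))
write.table(data.frame(human = sim$matrix$gene_names,
                       mouse = sim$truth$mouse_names),
            file.path(out, "ortholog_pairs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS(sim, "scratch/sim.rds")  # scratch only: exact object for later steps

ortho_truth <- simulate_ortholog_file(file.path(out, "orthologs_raw.txt.gz"),
                                      n_records = 2000L, n_strict = 1500L,
                                      n_prefix_only = 150L, seed = 1L)
gc_truth <- simulate_annotation(file.path(out, "toy.gtf"),
                                file.path(out, "toy.fa"),
                                n_genes = 50L, seed = 1L)

cat("Simulated", nrow(sim$matrix$values), "gene pairs x",
    ncol(sim$matrix$values), "samples in",
    length(unique(sim$metadata$batch)), "batches\n")
cat("Ortholog file:", ortho_truth$n_strict, "true one-to-one records,",
    ortho_truth$n_prefix - ortho_truth$n_strict, "prefix traps\n")
cat("Toy annotation:", nrow(gc_truth), "genes with planted GC\n")
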