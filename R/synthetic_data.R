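#' Synthetic confounded-design study generator
#'
#' Emulates the study this package is built to dissect: 26 samples (13
#' tissues x 2 species) sequenced in 5 batches, with two human-only batches
#' sharing a run and flowcell (differing only in lane), one mixed batch, and
#' two mouse-only batches on other instruments — so batch is nearly
#' completely confounded with species. Counts are negative-binomial with
#' additive log2-scale tissue, species and batch effects, per-batch noise
#' scale jitter, sample-specific GC bias and log-normal library sizes. All
#' ground truth is recorded so every pipeline stage can be checked exactly.
#'
#' @param n_genes number of ortholog gene pairs.
#' @param n_tissues tissues per species.
#' @param sd_tissue,sd_species,sd_batch standard deviations (log2 scale) of
#'   the planted tissue, species and batch location effects.
#' @param batch_scale_sd log-sd of the per-batch multiplicative jitter on
#'   the residual noise scale (exercises scale-effect shrinkage).
#' @param log_noise_sd log2-scale residual technical noise standard
#'   deviation (beyond counting noise).
#' @param base_log2_mean,base_log2_sd distribution of per-gene baseline
#'   log2 expression; the default centers per-gene depth near 1,000
#'   fragments, the coverage a multiplexed HiSeq lane delivers per gene at
#'   this gene count.
#' @param gc_bias_amplitude sd of the per-sample log-linear GC bias slope.
#' @param libsize_log_sd log-sd of the relative library sizes.
#' @param nb_dispersion negative-binomial dispersion (variance = mu +
#'   dispersion * mu^2); `0` means deterministic rounded means.
#' @param n_mito number of high-expressed mitochondrial genes planted.
#' @param n_retired number of retired identifiers planted per species.
#' @param batch_layout a layout as from [figure1_layout()].
#' @param seed integer; fully determines every output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, n_tissues = 13L,
                       sd_tissue = 1.0, sd_species = 0.5, sd_batch = 2.0,
                       batch_scale_sd = 0.2, log_noise_sd = 0.2,
                       base_log2_mean = 10, base_log2_sd = 2,
                       gc_bias_amplitude = 0.5, libsize_log_sd = 0.3,
                       nb_dispersion = 0.01, n_mito = 12L, n_retired = 27L,
                       batch_layout = figure1_layout(n_tissues),
                       seed = 1L) {
  stopifnot(sd_tissue >= 0, sd_species >= 0, sd_batch >= 0,
            batch_scale_sd >= 0, log_noise_sd >= 0, libsize_log_sd >= 0,
            nb_dispersion >= 0, n_genes > n_mito)
  structure(as.list(environment()), class = "sim_config")
}

#' The confounded five-batch layout
#'
#' Two human-only batches on one sequencer sharing run and flowcell
#' (differing only in lane), one mixed human+mouse batch, and two mouse-only
#' batches on two further instruments: four sequencers, five batches, one of
#' them mixed. Batch sizes are parameters of the layout, not constants: the
#' split of tissues across batches can be changed via `human_split`.
#'
#' The mixed batch holds the last two human tissues together with the
#' *first two* mouse tissues, and the mouse-only batches are shifted two
#' tissues relative to the human-only ones, so each pure-batch pair has a
#' nearly identical — not identical — tissue composition. That misalignment
#' keeps the batch + species + tissue model full rank (18 columns at 13
#' tissues): with perfectly aligned splits (a mixed lane holding the same
#' tissues from both species), a union of batch indicators equals a union
#' of tissue indicators and the model is singular. The mixed batch also
#' needs at least 4 samples; with only 2 the least-squares fit interpolates
#' them exactly, leaving no residual information to estimate that batch's
#' scale effect.
#'
#' @param n_tissues tissues per species.
#' @param human_split number of tissues in the first human-only batch.
#' @return data.frame with one row per sample: `sample_id`, `species`,
#'   `tissue`, `batch`, `machine_id`, `run_number`, `flowcell_id`, `lane`.
#' @export
figure1_layout <- function(n_tissues = 13L, human_split = 6L) {
  stopifnot(n_tissues >= 6L, human_split >= 2L, human_split <= n_tissues - 4L)
  tis <- sprintf("tissue%02d", seq_len(n_tissues))
  mk <- function(species, tissues, batch, machine, run, fc, lane)
    data.frame(sample_id = paste(species, tis[tissues], sep = "_"),
               species = species, tissue = tis[tissues], batch = batch,
               machine_id = machine, run_number = run, flowcell_id = fc,
               lane = lane, stringsAsFactors = FALSE)
  rbind(
    mk("human", seq_len(human_split), 1L, "HWI-SEQA", 101L, "C1AAAACXX", 4L),
    mk("human", (human_split + 1L):(n_tissues - 2L), 2L,
       "HWI-SEQA", 101L, "C1AAAACXX", 5L),
    mk("human", (n_tissues - 1L):n_tissues, 3L,
       "D4LHBFN1", 276L, "C2HKJACXX", 4L),
    mk("mouse", 1:2, 3L, "D4LHBFN1", 276L, "C2HKJACXX", 4L),
    mk("mouse", 3L:(human_split + 2L), 4L, "HWI-SEQC", 310L, "C3BBBBCXX", 2L),
    mk("mouse", (human_split + 3L):n_tissues, 5L,
       "HWI-SEQD", 412L, "C4CCCCCXX", 7L))
}

#' Simulate the confounded-study count matrix
#'
#' Log2 mean for gene g in sample j:
#' `base_g + tissue_eff[g, t(j)] + species_eff[g, s(j)] + batch_loc[g, b(j)]
#' + scale_b(j) * eps[g, j]`, with counts drawn negative-binomial around
#' `libsize_j * gc_bias_j(gc_g) * 2^mean`. Mitochondrial genes get a high
#' baseline so they rank in the top expression stratum, as in real data.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (an [expr_matrix()] of raw counts with
#'   library-size proxies = its column sums), `metadata` (sample table with
#'   batch and identifier lines), `truth` (every planted quantity) and
#'   `gc_human`, `gc_mouse` (GC tables including the planted retired ids).
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  layout <- cfg$batch_layout
  missing_sp <- setdiff(unique(layout$tissue),
                        layout$tissue[layout$species == "human"])
  if (length(setdiff(unique(layout$tissue),
                     layout$tissue[layout$species == "mouse"])) ||
      length(missing_sp))
    stop("invalid layout: every tissue needs both species")
  n <- cfg$n_genes
  ns <- nrow(layout)
  B <- length(unique(layout$batch))
  tissues <- sort(unique(layout$tissue))

  human_names <- sprintf("GENE%05d", seq_len(n))
  mouse_names <- sprintf("Gene%05d", seq_len(n))
  mito_idx <- sample.int(n, cfg$n_mito)
  human_names[mito_idx] <- sprintf("MT-H%02d", seq_len(cfg$n_mito))
  mouse_names[mito_idx] <- sprintf("mt-M%02d", seq_len(cfg$n_mito))

  gc <- 0.2 + 0.6 * stats::rbeta(n, 2, 2)
  base <- stats::rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd)
  # mitochondrial transcripts are heavily overrepresented in real libraries
  base[mito_idx] <- stats::rnorm(cfg$n_mito, cfg$base_log2_mean + 4, 0.5)
  tissue_eff <- matrix(stats::rnorm(n * length(tissues), 0, cfg$sd_tissue),
                       n, length(tissues), dimnames = list(NULL, tissues))
  species_eff <- matrix(stats::rnorm(n * 2, 0, cfg$sd_species), n, 2,
                        dimnames = list(NULL, c("human", "mouse")))
  batch_loc <- matrix(stats::rnorm(n * B, 0, cfg$sd_batch), n, B)
  batch_scale <- exp(stats::rnorm(B, 0, cfg$batch_scale_sd))
  libsize <- exp(stats::rnorm(ns, 0, cfg$libsize_log_sd))
  gc_slope <- stats::rnorm(ns, 0, cfg$gc_bias_amplitude)

  counts <- matrix(0, n, ns)
  for (j in seq_len(ns)) {
    b <- layout$batch[j]
    log2mu <- base +
      tissue_eff[, layout$tissue[j]] +
      species_eff[, layout$species[j]] +
      batch_loc[, b] +
      batch_scale[b] * stats::rnorm(n, 0, cfg$log_noise_sd)
    mu <- libsize[j] * exp(gc_slope[j] * (gc - 0.5)) * 2^log2mu
    counts[, j] <- if (cfg$nb_dispersion > 0)
      stats::rnbinom(n, mu = mu, size = 1 / cfg$nb_dispersion)
    else round(mu)
  }

  metadata <- layout
  metadata$identifier_line <- simulate_fastq_headers(layout)
  m <- expr_matrix(counts, gene_names = human_names,
                   sample_ids = layout$sample_id, value_kind = "raw_count",
                   library_size_proxy = stats::setNames(colSums(counts),
                                                        layout$sample_id))
  gc_tabs <- plant_gc_tables(n, human_names, mouse_names, gc, cfg$n_retired)
  truth <- list(base = base, gc = gc, tissue_eff = tissue_eff,
                species_eff = species_eff, batch_loc = batch_loc,
                batch_scale = batch_scale, libsize = libsize,
                gc_slope = gc_slope,
                mito_genes = human_names[mito_idx],
                mito_genes_mouse = mouse_names[mito_idx],
                mouse_names = mouse_names,
                retired_human = gc_tabs$retired_human,
                retired_mouse = gc_tabs$retired_mouse,
                column_sums = colSums(counts))
  list(matrix = m, metadata = metadata, truth = truth,
       gc_human = gc_tabs$human, gc_mouse = gc_tabs$mouse)
}

# GC tables carrying, after the real identifiers, retired identifiers that
# share the common names of the first genes (retained-in-GTF,
# removed-from-database ids — the collision source the matrix builder must
# survive).
plant_gc_tables <- function(n, human_names, mouse_names, gc, n_retired) {
  hum_ids <- sprintf("ENSG%011d", seq_len(n))
  mou_ids <- sprintf("ENSMUSG%011d", seq_len(n))
  retired_h <- sprintf("ENSG%011d", n + seq_len(n_retired))
  retired_m <- sprintf("ENSMUSG%011d", n + seq_len(n_retired))
  human <- data.frame(
    gene_id = c(hum_ids, retired_h),
    common_name = c(human_names, human_names[seq_len(n_retired)]),
    gc_fraction = c(gc, gc[seq_len(n_retired)]),
    unambiguous_length = 1000L, stringsAsFactors = FALSE)
  mouse <- data.frame(
    gene_id = c(mou_ids, retired_m),
    common_name = c(mouse_names, mouse_names[seq_len(n_retired)]),
    gc_fraction = c(gc, gc[seq_len(n_retired)]),
    unambiguous_length = 1000L, stringsAsFactors = FALSE)
  list(human = human, mouse = mouse,
       retired_human = retired_h, retired_mouse = retired_m)
}

#' Per-sample quantification tables from a simulated study
#'
#' Rewrites the simulated count matrix as featureCounts-like per-sample
#' tables keyed by species-specific gene identifiers, with the planted
#' retired identifiers included (carrying nonzero values that a correct
#' builder must drop).
#'
#' @param sim result of [simulate_counts()].
#' @param retired_value count value planted on every retired identifier row.
#' @return named list of data.frames (`gene_id`, `value`), one per sample.
#' @export
simulate_quant_tables <- function(sim, retired_value = 5) {
  n <- nrow(sim$matrix$values)
  out <- list()
  for (j in seq_along(sim$metadata$sample_id)) {
    sp <- sim$metadata$species[j]
    gc_tab <- if (sp == "human") sim$gc_human else sim$gc_mouse
    retired <- if (sp == "human") sim$truth$retired_human
    else sim$truth$retired_mouse
    out[[sim$metadata$sample_id[j]]] <-
      data.frame(gene_id = c(gc_tab$gene_id[seq_len(n)], retired),
                 value = c(sim$matrix$values[, j],
                           rep(retired_value, length(retired))),
                 stringsAsFactors = FALSE)
  }
  out
}

#' Generate FASTQ identifier lines realizing a batch layout
#'
#' @param layout a layout table (see [figure1_layout()]); tile/x/y and index
#'   sequences are drawn at random, the batch-defining fields come from the
#'   layout, so batch inference on the output recovers the layout exactly.
#' @param reads_per_sample lines per sample.
#' @return with `reads_per_sample = 1`, a character vector (one line per
#'   sample); otherwise a list of character vectors.
#' @export
simulate_fastq_headers <- function(layout, reads_per_sample = 1L) {
  lines <- lapply(seq_len(nrow(layout)), function(j) {
    vapply(seq_len(reads_per_sample), function(k) {
      sprintf("@%s:%d:%s:%d:%d:%d:%d 1:N:0:%s",
              layout$machine_id[j], layout$run_number[j],
              layout$flowcell_id[j], layout$lane[j],
              sample(1101:2316, 1), sample.int(20000, 1),
              sample.int(200000, 1),
              paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                    collapse = ""))
    }, "")
  })
  if (reads_per_sample == 1L) vapply(lines, `[[`, "", 1L) else lines
}

#' Write a synthetic modENCODE-style ortholog file
#'
#' Records end with two count columns; one-to-one pairs have both exactly
#' "1". `n_prefix_only` trap records have a last column that merely *begins*
#' with 1 (a 1-to-10/12/15/19 group, self-consistent with its gene list), so
#' a lax selection admits them. Remaining records get other count
#' combinations and survive neither parse mode.
#'
#' @param path output path (`.gz` for gzip).
#' @param n_records,n_strict,n_prefix_only record counts.
#' @param seed integer seed.
#' @return invisibly, the ground truth: planted strict/prefix counts and the
#'   strict pair list.
#' @export
simulate_ortholog_file <- function(path, n_records = 2000L, n_strict = 1500L,
                                   n_prefix_only = 150L, seed = 1L) {
  stopifnot(n_strict + n_prefix_only <= n_records)
  set.seed(seed)
  type <- sample(c(rep("strict", n_strict), rep("prefix", n_prefix_only),
                   rep("other", n_records - n_strict - n_prefix_only)))
  hum <- sprintf("ORTH_H%05d", seq_len(n_records))
  mou <- sprintf("Orth_m%05d", seq_len(n_records))
  lines <- character(n_records)
  for (i in seq_len(n_records)) {
    if (type[i] == "strict") {
      lines[i] <- paste(hum[i], mou[i], "1", "1", sep = "\t")
    } else if (type[i] == "prefix") {
      k <- sample(c(10L, 12L, 15L, 19L), 1)
      ml <- paste(paste0(mou[i], letters[seq_len(k)]), collapse = ",")
      lines[i] <- paste(hum[i], ml, "1", k, sep = "\t")
    } else {
      nh <- sample(2:4, 1); nm <- sample(2:4, 1)
      hl <- paste(paste0(hum[i], LETTERS[seq_len(nh)]), collapse = ",")
      ml <- paste(paste0(mou[i], letters[seq_len(nm)]), collapse = ",")
      lines[i] <- paste(hl, ml, nh, nm, sep = "\t")
    }
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  invisible(list(n_strict = n_strict,
                 n_prefix = n_strict + n_prefix_only,
                 strict_pairs = data.frame(human = hum[type == "strict"],
                                           mouse = mou[type == "strict"],
                                           stringsAsFactors = FALSE)))
}

#' Write a toy GTF + FASTA pair with known per-gene GC
#'
#' Genes of 1-5 transcripts with deliberately overlapping exons are placed
#' on short random chromosomes; some genes get planted runs of N. The GC of
#' each gene's exon union is computed at planting time by direct base
#' counting on the generated sequence.
#'
#' @param gtf,fasta output paths.
#' @param n_genes genes to plant.
#' @param seed integer seed.
#' @param include_all_n also plant one gene whose exons are entirely N.
#' @return invisibly, the truth table: `gene_id`, `common_name`,
#'   `gc_fraction`, `unambiguous_length`.
#' @export
simulate_annotation <- function(gtf, fasta, n_genes = 50L, seed = 1L,
                                include_all_n = FALSE) {
  set.seed(seed)
  genes_per_chrom <- 25L
  n_all <- n_genes + as.integer(include_all_n)
  n_chrom <- ceiling(n_all / genes_per_chrom)
  chrom_names <- paste0("chrT", seq_len(n_chrom))
  chrom_seq <- list()
  gtf_lines <- character()
  truth <- data.frame(gene_id = character(), common_name = character(),
                      gc_fraction = numeric(), unambiguous_length = integer(),
                      stringsAsFactors = FALSE)
  for (ci in seq_len(n_chrom)) {
    seq_chars <- character(0)
    pos <- 1L
    first <- (ci - 1L) * genes_per_chrom + 1L
    last <- min(ci * genes_per_chrom, n_all)
    for (g in first:last) {
      gid <- sprintf("ENSTOY%07d", g)
      gname <- sprintf("TOY%04d", g)
      all_n_gene <- include_all_n && g == n_all
      glen <- sample(200:600, 1)
      gene_seq <- if (all_n_gene) rep("N", glen)
      else sample(c("A", "C", "G", "T", "a", "c", "g", "t", "N"), glen,
                  replace = TRUE,
                  prob = c(.2, .2, .2, .2, .04, .04, .04, .04, .04))
      gstart <- pos + sample(20:60, 1)
      seq_chars <- c(seq_chars, rep("A", gstart - pos), gene_seq)
      pos <- gstart + glen
      # exon pool, then 1-5 transcripts each drawing overlapping subsets
      n_ex <- sample(2:5, 1)
      bounds <- sort(sample(seq_len(glen - 1L), 2L * n_ex, replace = FALSE))
      exons <- cbind(bounds[seq(1, 2 * n_ex, 2)], bounds[seq(2, 2 * n_ex, 2)])
      n_tx <- sample(1:5, 1)
      used <- rep(FALSE, n_ex)
      for (t in seq_len(n_tx)) {
        pick <- sort(sample.int(n_ex, sample.int(n_ex, 1)))
        used[pick] <- TRUE
        for (e in pick) {
          # jitter transcript exon ends inward to create partial overlaps
          s <- min(exons[e, 1] + sample(0:2, 1), exons[e, 2])
          en <- max(s, exons[e, 2] - sample(0:2, 1))
          gtf_lines <- c(gtf_lines, sprintf(
            '%s\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.t%d"; gene_name "%s";',
            chrom_names[ci], gstart + s - 1L, gstart + en - 1L,
            gid, gid, t, gname))
        }
      }
      # ensure at least one transcript covers every pooled exon exactly,
      # making the planted union the exon-pool union
      for (e in seq_len(n_ex)) {
        gtf_lines <- c(gtf_lines, sprintf(
          '%s\tsim\texon\t%d\t%d\t.\t+\t.\tgene_id "%s"; transcript_id "%s.t0"; gene_name "%s";',
          chrom_names[ci], gstart + exons[e, 1] - 1L,
          gstart + exons[e, 2] - 1L, gid, gid, gname))
      }
      covered <- rep(FALSE, glen)
      for (e in seq_len(n_ex)) covered[exons[e, 1]:exons[e, 2]] <- TRUE
      bases <- toupper(gene_seq[covered])
      n_gc <- sum(bases %in% c("G", "C"))
      n_acgt <- sum(bases %in% c("A", "C", "G", "T"))
      truth <- rbind(truth, data.frame(
        gene_id = gid, common_name = gname,
        gc_fraction = if (n_acgt > 0) n_gc / n_acgt else NA_real_,
        unambiguous_length = n_acgt, stringsAsFactors = FALSE))
    }
    chrom_seq[[chrom_names[ci]]] <- paste(seq_chars, collapse = "")
  }
  fa <- character()
  for (nm in names(chrom_seq)) fa <- c(fa, paste0(">", nm), chrom_seq[[nm]])
  writeLines(fa, fasta)
  writeLines(gtf_lines, gtf)
  invisible(truth)
}
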