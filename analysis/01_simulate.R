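#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study dataset.
#
# Builds a guide-site-free background genome, plants a 2,000-gene
# protein-coding pool whose upstream windows carry guide sites at
# 0.215 sites/kb (background) and an 18-gene designated set at
# 0.409 sites/kb, then draws per-sample ATAC-style peak sets with
# site-bearing probabilities 0.008 (control) / 0.019 (treated).
# All files land in results/dataset/, ground truth in truth.json.

suppressMessages(library(guidesites))

outdir <- "results/dataset"
cfg <- synth_config(seed = 20260925L)

ds <- simulate_dataset(cfg, outdir)

cat("genome:        ", genome_total_length(ds$genome), "bp over",
    length(ds$genome), "contigs\n")
cat("pool genes:    ", nrow(ds$genes), "\n")
cat("enriched set:  ", length(ds$truth$enriched_gene_ids), "genes\n")
cat("planted sites: ", nrow(ds$truth$planted_sites), "\n")
cat("peak samples:  ", length(ds$peaks_by_sample), "x",
    cfg$peaks_per_sample, "peaks\n")
cat("files written under", outdir, "\n")
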