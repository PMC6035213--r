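#!/usr/bin/env Rscript
# Stage 3: TSS-window density statistic and Monte Carlo enrichment test.
#
# For the designated gene set, computes the mean number of guide sites
# per kb in each gene's -10 kb/+1 kb TSS window and tests it against
# 100,000 equally sized sets resampled from the full pool.

suppressMessages(library(guidesites))

dir <- "results/dataset"
genome <- read_fasta(file.path(dir, "genome.fa"))
genes <- read_genes(file.path(dir, "genes.tsv"), genome = genome)
guide <- read_guides(file.path(dir, "guides.tsv"))[[1]]
set_ids <- read_gene_set(file.path(dir, "enriched_set.txt"))

res <- run_enrichment(genome, genes, guide, set_ids,
                      window = window_spec(10, 1),
                      n_perm = 1e5, seed = 99L)
print(res)

pool_hits <- find_guide_sites(genome, guide)
pool <- set_mean_density(genes, pool_hits, window_spec(10, 1), genome,
                         set_id = "pool")
print(pool)

write_result_json(res, "results/enrichment.json",
                  manifest = run_manifest("enrich",
                                          inputs = file.path(dir, c("genome.fa", "genes.tsv",
                                                                    "guides.tsv", "enriched_set.txt")),
                                          seed = 99L))
cat("report written to results/enrichment.json\n")
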