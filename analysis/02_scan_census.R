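#!/usr/bin/env Rscript
# Stage 2: genome-wide guide-site census.
#
# Rescans the emitted genome from stage 1 with the guide from its
# guides.tsv, writes the hits as BED6 plus a JSON census, and checks the
# count against the generator's planted truth.

suppressMessages(library(guidesites))

dir <- "results/dataset"
genome <- read_fasta(file.path(dir, "genome.fa"))
guide <- read_guides(file.path(dir, "guides.tsv"))[[1]]

hits <- find_guide_sites(genome, guide)
write_hits_bed(hits, file.path("results", "sites.bed"))

census <- list(guide = guide$name,
               n_sites = nrow(hits),
               by_strand = as.list(table(hits$strand)),
               genome_bp = genome_total_length(genome),
               sites_per_mb = nrow(hits) / (genome_total_length(genome) / 1e6))
write_result_json(census, file.path("results", "census.json"),
                  manifest = run_manifest("scan",
                                          inputs = file.path(dir, c("genome.fa", "guides.tsv"))))

truth <- jsonlite::read_json(file.path(dir, "truth.json"))
cat("sites found:  ", census$n_sites, "\n")
cat("planted truth:", length(truth$planted_sites), "\n")
stopifnot(census$n_sites == length(truth$planted_sites))
cat("scanner output equals planted truth; census written to results/census.json\n")
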