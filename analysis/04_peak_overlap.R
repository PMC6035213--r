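#!/usr/bin/env Rscript
# Stage 4: ATAC-peak / guide-site overlap comparison.
#
# For every sample in the sheet, computes the fraction of peaks
# containing at least one guide site, then compares control and treated
# groups with a pooled-variance two-tailed Student's t-test.

suppressMessages(library(guidesites))

dir <- "results/dataset"
genome <- read_fasta(file.path(dir, "genome.fa"))
guide <- read_guides(file.path(dir, "guides.tsv"))[[1]]
sheet <- read.delim(file.path(dir, "sample_sheet.tsv"))

oc <- run_peak_overlap(genome, guide, sheet, dir = dir)
print(oc)
cat("per-sample fractions:\n")
print(round(100 * oc$per_sample_fraction, 2))

write_result_json(oc, "results/peak_overlap.json",
                  manifest = run_manifest("peaks",
                                          inputs = file.path(dir, c("genome.fa", "guides.tsv",
                                                                    "sample_sheet.tsv"))))
cat("report written to results/peak_overlap.json\n")
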