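#!/usr/bin/env Rscript
# Stage 5: protospacer tiling of a motif consensus.
#
# Enumerates every 14-nt protospacer with an NGG PAM on both strands of a
# 36-bp consensus-like query and ranks the candidates by the number of
# disfavoured PAM-proximal bases (example table; the disfavoured set is
# configuration, not a shipped default).

suppressMessages(library(guidesites))

dir <- "results/dataset"
guide <- read_guides(file.path(dir, "guides.tsv"))[[1]]

# a consensus-like query: the planted protospacer in a 36-bp context
set.seed(1)
flank <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
query <- paste0(flank(8), guide$protospacer, "AGG", flank(11))
cat("query (", nchar(query), " nt): ", query, "\n", sep = "")

cand <- enumerate_protospacers(query, guide_len = 14, pam = "NGG")
example_table <- list("1" = "T", "2" = c("T", "G"), "3" = "T", "4" = "T")
cand <- rank_candidates(cand, example_table, k = 4)
print(cand)

dir.create("results", showWarnings = FALSE)
write.table(cand, "results/guide_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("candidates written to results/guide_candidates.tsv\n")
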