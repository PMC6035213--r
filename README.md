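# guidesites

Genome-wide CRISPR guide target-site scanning and TSS-window enrichment
statistics, with a planted-truth synthetic-genome generator.

## The problem

CRISPRa experiments that target a repetitive regulatory motif — e.g. a
conserved 36-bp segment of the Alu element, bound by a short 14-nt guide —
need two computational answers:

1. **Promoter enrichment.** Are the guide's target sites (protospacer +
   PAM occurrences) denser in the −10 kb/+1 kb TSS windows of a gene set
   than expected for an equally sized set drawn from the protein-coding
   pool?  The statistic is the unweighted mean of per-gene densities
   $d_i = n_i / w_i$ (sites per kb in gene *i*'s window), tested against
   a Monte Carlo null: $B = 10^5$ resamples of *n* genes without
   replacement from the pool, $\hat p = \#\{\bar d_b \ge \bar d_{obs}\}/B$
   (upper tail).
2. **Chromatin opening.** Does the fraction of ATAC-seq peaks containing
   at least one guide site differ between control and treated samples?
   Per-sample fractions are compared with a pooled-variance two-tailed
   Student's t-test.

Both statistics are validated end to end against a synthetic-genome
generator that plants sites at controlled per-kb densities inside
TSS-anchored windows and emits peak sets with controlled site-bearing
fractions — under sanitization, the scanner's output equals the planted
truth exactly, so recovery is checkable to the last site.

Users: regulatory-genomics analysts working with guide RNAs against
repeat-derived motifs; anyone needing a seeded, oracle-tested
site-density enrichment pipeline.

## Worked example

The `analysis/` directory holds the numbered pipeline drivers; each is a
thin script over the package functions and writes its report under
`results/`.

```sh
Rscript analysis/01_simulate.R      # synthetic dataset -> results/dataset/
Rscript analysis/02_scan_census.R   # genome-wide site census + BED
Rscript analysis/03_enrichment.R    # density + Monte Carlo test
Rscript analysis/04_peak_overlap.R  # ATAC peak/site overlap comparison
Rscript analysis/05_guide_design.R  # protospacer tiling of a consensus
```

Stage 1 generates a 22.4-Mb genome hosting a 2,000-gene pool whose
TSS windows carry a 14-nt guide's sites at 0.215 sites/kb, with a
designated 18-gene set at 0.409 sites/kb.  Stage 3 then prints:

```
Monte Carlo enrichment 'observed': observed mean 0.4192 sites/kb (n = 18)
  pool 2000 genes, 100000 permutations, exceedances 0, P < 1e-05
Gene-set density 'pool': mean 0.2120 sites/kb over 2000 genes (0 excluded)
```

The designated set's recovered mean (0.419 sites/kb) matches its planting
rate, the pool mean (0.212) matches the background rate, and no
permutation of 18 pool genes reaches the observed mean, so the empirical
p-value is below the $10^{-5}$ resolution of $10^5$ permutations.
Stage 4 prints:

```
Peak overlap: control 1.03% (n = 3) vs treated 1.72% (n = 5)
  pooled t = 2.222, df = 6, two-tailed P = 0.068
```

i.e. the per-sample fraction of 1,000 peaks containing a guide site,
generated at site-bearing probabilities 0.8% (control) and 1.9%
(treated); with 3-vs-5 samples a single seed may or may not cross
$p < 0.05$ — the 20-seed recovery experiment in the acceptance suite
shows the group means are recovered to within a small fraction of a
percentage point.

Equivalent calls in R:

```r
library(guidesites)
cfg <- synth_config(seed = 1)                     # study-scale defaults
pl  <- plant_gene_sites(generate_background(cfg), cfg)
mc  <- run_enrichment(pl$genome, pl$genes, cfg$guide,
                      pl$truth$enriched_gene_ids, n_perm = 1e5, seed = 1,
                      hits = pl$hits)
```

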