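---
title: "Guide target-site density near TSSs: model, null and synthetic validation"
author: "guidesites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide target-site density near TSSs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidesites)
```

## The question

CRISPR activation (CRISPRa) experiments that target a repetitive regulatory
motif — such as a conserved segment of the Alu SINE element — raise a
quantitative question: are the motif's guide-RNA target sites *enriched*
near the transcription start sites (TSSs) of a particular gene set, beyond
what the genome-wide background would produce?  A companion question arises
from ATAC-seq: does the fraction of open-chromatin peaks containing a guide
site differ between dCas9-induced and control samples?

`guidesites` implements the full computational chain for both questions:

1. exhaustive, strand-aware scanning of a genome for a guide's target
   sites (protospacer immediately followed by a PAM),
2. a per-gene site-density statistic in a TSS-anchored window,
3. a Monte Carlo resampling null over a protein-coding gene pool,
4. a per-sample peak/site overlap fraction with a two-group Student's
   t-test, and
5. a synthetic-genome generator that plants sites at controlled densities
   so every statistic can be validated against known truth.

## Site definition and scanning

A *site* for guide $g$ with protospacer $s$ (length $L \ge 10$, bases
A/C/G/T only) and PAM pattern $\pi$ (IUPAC, default `NGG`) is any genomic
position, on either strand, where $s$ occurs exactly and is immediately
followed 3′ by a match to $\pi$.  Matching is exact: no mismatches are
tolerated, and an `N` in the genome matches nothing — a site interrupted
by assembly gaps does not count.  Overlapping occurrences are each
reported.  The PAM is required everywhere, including the genome-wide
census, because a dCas9 binding site without a PAM is not functional; the
`require_pam = FALSE` switch exists only for sensitivity checks, since
published census figures do not always state whether a PAM was demanded.

All coordinates are 0-based half-open (BED convention) on the forward
strand; a hit records the protospacer interval only, so `end - start`
always equals $L$.  A hit's window membership is decided by its forward
start coordinate, a deliberately strand-independent tie-break at window
edges.

The scanner is `Biostrings::matchPattern()` with the pattern's IUPAC
codes active and the subject treated literally, followed by a filter that
drops any hit whose genomic span contains `N` (Biostrings would otherwise
let a pattern `N` match a literal subject `N`).  The test suite holds the
scanner to an independent exhaustive sliding-window oracle (plain string
and regex machinery) on random genomes up to 100 kb, plus strand-symmetry
and determinism properties.

## The density statistic

For gene $i$ with TSS $t_i$ on a contig of length $C$, the analysis
window is

$$W_i = \begin{cases}[t_i - 10\,000,\; t_i + 1\,000) & \text{strand } +\\
[t_i - 1\,000,\; t_i + 10\,000) & \text{strand } -\end{cases}$$

clipped to $[0, C)$; the defaults (10 kb upstream, 1 kb downstream) are
the package's `window_spec(10, 1)` and can be changed.  The per-gene
density is $d_i = n_i / w_i$, with $n_i$ the number of hit starts in
$W_i$ and $w_i$ the clipped window length in kb.  A gene set's statistic
is the **unweighted arithmetic mean** $\bar d = \frac1n \sum d_i$.  The
aggregate alternative $\sum n_i / \sum w_i$ is implemented
(`mean_type = "aggregate"`) because the phrasing "mean per kb over $n$
genes" is ambiguous between the two; the per-gene mean is the default as
it matches that phrasing most directly and weights every gene equally.
Genes whose window clips below 1 kb are excluded (with a logged count)
from sets and pool alike: a nearly empty window turns a single site into
an extreme density and the exclusion rule is stated nowhere upstream, so
the package errs on the side of robustness.

## The Monte Carlo null

The significance of an observed set mean $\bar d_{obs}$ ($n$ genes) is
assessed against the pool of protein-coding genes: pool densities are
computed once, then each of $B$ permutations (default $B = 10^5$) draws
$n$ genes uniformly *without replacement from the full pool* (observed
genes are not excluded — plain subsampling) and records the mean of the
precomputed densities.  The p-value is the upper-tail exceedance fraction

$$\hat p = \frac{\#\{b : \bar d_b \ge \bar d_{obs}\}}{B},$$

one-sided because the question is enrichment.  When no permutation
reaches the observed mean the result is flagged `p < 1/B` rather than
claiming zero; the positively biased estimator $(k+1)/(B+1)$ is available
via `estimator = "add_one"`.  Every result records its seed and $B$.
Correctness is checked two ways: exact subset enumeration on pools of
$\le 10$ genes (the Monte Carlo estimate must sit within 3 binomial
standard errors of the exact p), and a Kolmogorov–Smirnov check that
pool-resampled "null sets" give approximately uniform p-values.

## Peak overlap comparison

For one sample, the statistic is the fraction of peaks whose interval
intersects at least one protospacer interval by $\ge 1$ bp on the same
contig; a peak counts once however many sites it contains.  Whether the
upstream analysis demanded full containment is not documented, so
`mode = "within"` (protospacer fully inside the peak) is available;
any-intersection is the default as the standard BED-style convention.
Groups are compared with the classical pooled-variance two-sample
two-tailed Student's t-test on the untransformed fractions — matching the
named test rather than Welch's variant, which is available via
`welch = TRUE`.  Zero pooled variance is handled explicitly: equal means
give $p = 1$, unequal means report $p = 0$ with a below-machine flag.

## Guide tiling

`enumerate_protospacers()` tiles both strands of a query (e.g. a 36-bp
motif consensus) for fixed-length protospacers (14 nt in the motivating
design — truncated guides) adjacent to a PAM, and
`pam_proximal_report()` counts how many of the $k$ bases nearest the PAM
(default $k = 4$, position 1 adjacent to the PAM) fall in a user-supplied
disfavoured-base table.  No default table is shipped: the underlying
efficacy rule comes from external work that the package does not
reproduce, so asserting one would invent ground truth.  Ranking is
transparent — ascending disfavoured count, ties by offset — and no
machine-learned efficacy score is attempted.

## The synthetic-data generator

The generator exists so that every statistic above can be validated
against planted truth, and its defaults *are* the validation conditions
used throughout the tests:

| parameter | default | meaning |
|---|---|---|
| `pool_size` | 2,000 | protein-coding pool genes |
| `background_density` | 0.215 /kb | pool planting rate |
| `enriched_set_size`, `enriched_density` | 18, 0.409 /kb | designated enriched set |
| `window` | 10 kb / 1 kb | TSS window |
| `guide` | 14-nt protospacer, `NGG` | planted site class |
| `gc_content` | 0.41 | human-like background GC |
| `peaks_per_sample` | 1,000 | per-sample ATAC-style peaks |
| `n_control_samples`, `control_overlap_fraction` | 3, 0.008 | control group |
| `n_treated_samples`, `treated_overlap_fraction` | 5, 0.019 | treated group |
| `peak_width` | 400 bp | typical ATAC peak width |

The 2,000-gene pool is a desk-scale stand-in for a full ~20,000-gene
protein-coding annotation: it keeps a 50-seed recovery experiment under
three minutes on one CPU while leaving the set-vs-pool inference
structurally identical.  Additional designated sets with their own rates
(13 genes at 0.280 /kb and 15 at 0.224 /kb in the validation suite,
mirroring reported non-enriched sets) are planted disjointly via
`extra_sets`.

Generation proceeds in three stages, each seeded from the master seed:

* **Background** — i.i.d. bases at the target GC (realised through a
  1000-slot lookup, so the fraction is honoured to 3 decimals).  With
  `sanitize = TRUE` every accidental protospacer+PAM occurrence is
  destroyed by resampling one base inside it, iterating until the scanner
  finds zero hits; local resampling (rather than rejecting whole genomes)
  terminates quickly for any non-degenerate guide and leaves GC
  essentially untouched, since for a 14+3-nt site in tens of Mb the
  expected number of accidental hits is well below one.
* **Planting** — TSS windows are laid out as non-overlapping tiles across
  contigs (window geometry identical for every gene, so no clipping);
  strands are random; each gene's site count is drawn
  $\mathrm{Poisson}(\text{density} \times 11\ \text{kb})$ — the simplest
  count model consistent with a per-kb rate, and an explicit assumption
  of this module, not a claim about real Alu placement; sites are written
  at uniform non-overlapping positions within the window, each on a
  random strand, with the PAM realised concretely (`AGG` for `NGG`).
  After planting, the genome is re-sanitised around the planted spans so
  that junction-created spurious occurrences are destroyed: under
  `sanitize = TRUE` the scanner's output equals the planted truth
  *exactly*, which is what makes downstream recovery tests deterministic
  given the seed.
* **Peaks** — each peak is independently site-bearing with its group's
  probability; site-bearing peaks are centred on a uniformly chosen
  planted site (guaranteeing overlap for any `peak_width` at least the
  site length), the rest are placed at positions verified free of planted
  sites.  Realised per-sample fractions therefore equal the recorded
  truth counts divided by `peaks_per_sample` exactly.

What the generator does **not** emulate: clustered, lineage-structured
Alu placement (real Alu density is strongly non-Poisson and
GC-stratified), gene-length and promoter-composition heterogeneity,
chromatin state, and read-level noise in peak calls.  Passing recovery
tests therefore demonstrate that the *statistics* are computed correctly
and are well calibrated under their own null — not that the biological
enrichment conclusion transfers to any real genome.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; conversion to
  Biostrings/IRanges 1-based closed happens only at call boundaries.
* Window membership by hit start position: unambiguous, strand-independent
  edge handling.
* `sample_nonoverlapping()` places sites by rejection sampling; with at
  most ~10 17-bp sites per 11-kb window the failure probability is
  negligible, and failure raises an error rather than silently dropping
  sites.
* The pooled t statistic is computed in closed form so degenerate
  variances have defined behaviour; `stats::t.test(var.equal = TRUE)` is
  the cross-check in the tests on non-degenerate data.
* All stochastic entry points take explicit seeds (`withr::with_seed`),
  keep them below $2^{31}$, and record them in their results.
* Vectorised pool-density computation (`findInterval` over sorted hit
  starts) is held equal to the per-gene recomputation by a dedicated
  test.

## Problem sizes used in validation

Density recovery runs 50 seeded datasets at the default study scale
(2,000 genes, 22.4 Mb genome split over 4 contigs); the Monte Carlo test
uses $10^5$ permutations on the first dataset of that family; peak
recovery runs 20 seeded datasets with a 300-gene, 3.4 Mb genome, which
supplies ample planted sites for the ~8–19 site-bearing peaks a sample
draws while keeping the 20-replicate experiment under a minute.  Unit
tests use smaller genomes (0.1–1 Mb) chosen so each oracle comparison
stays exhaustive.

## Limitations

* Exact matching only; mismatch-tolerant (off-target) scanning is out of
  scope.
* The null resamples genes uniformly; no GC-, length- or
  distance-matched null is provided.
* The peak comparison is a plain two-group t-test on fractions; it does
  not model per-peak covariates or replicate structure.
* The generator's Poisson placement understates the clumping of real
  repeat families; a clustered placement mode would be the natural
  extension.
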