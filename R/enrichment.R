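#' TSS-anchored analysis window
#'
#' Defines the upstream region scanned for guide sites: by default 10 kb
#' upstream to 1 kb downstream of the TSS, mirrored for minus-strand genes
#' and clipped to the contig.
#'
#' @param upstream_kb,downstream_kb window extent in kb (defaults 10 and 1).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(upstream_kb = 10, downstream_kb = 1) {
  stopifnot(upstream_kb >= 0, downstream_kb >= 0,
            upstream_kb + downstream_kb > 0)
  structure(list(upstream_kb = upstream_kb, downstream_kb = downstream_kb),
            class = "window_spec")
}

#' Compute a gene's upstream window
#'
#' For a `+` gene the window is `[tss - up, tss + down)`; for a `-` gene
#' `[tss - down, tss + up)`; both clipped to `[0, contig_length)`.
#'
#' @param gene one-row gene data.frame (or list) with tss and strand.
#' @param spec a [window_spec()].
#' @param contig_length length of the gene's contig in bp.
#' @return list with `start`, `end` (0-based half-open) and `effective_kb`.
#' @export
upstream_window <- function(gene, spec = window_spec(), contig_length) {
  stopifnot(contig_length > 0)
  up <- round(spec$upstream_kb * 1000)
  down <- round(spec$downstream_kb * 1000)
  if (gene$strand == "+") {
    start <- gene$tss - up; end <- gene$tss + down
  } else {
    start <- gene$tss - down; end <- gene$tss + up
  }
  start <- max(0, start)
  end <- min(contig_length, end)
  if (end < start) end <- start
  list(start = start, end = end, effective_kb = (end - start) / 1000)
}

#' Per-gene upstream site density
#'
#' Number of guide-site hits whose protospacer start lies in the gene's
#' window, divided by the window's effective length in kb.
#'
#' @param hits sorted hit table.
#' @param gene one-row gene record.
#' @param spec a [window_spec()].
#' @param genome genome (for contig lengths).
#' @return density in sites/kb, or `NA` (with a warning) when the window
#'   clips to zero length.
#' @export
gene_density <- function(hits, gene, spec = window_spec(), genome) {
  len <- Biostrings::width(genome)[match(gene$contig, names(genome))]
  if (is.na(len)) stop("gene ", gene$gene_id, ": unknown contig ", gene$contig)
  w <- upstream_window(gene, spec, len)
  if (w$effective_kb == 0) {
    warning("gene ", gene$gene_id, ": window clipped to zero length; excluded")
    return(NA_real_)
  }
  sites_in_interval(hits, gene$contig, w$start, w$end) / w$effective_kb
}

# Vectorised per-gene densities for a gene table; genes whose window clips
# below `min_kb` get NA.  Equivalent to row-wise gene_density() (tested).
gene_densities_vec <- function(hits, genes, spec = window_spec(), genome,
                               min_kb = 0) {
  assert_hits_sorted(hits)
  lens <- setNames(Biostrings::width(genome), names(genome))
  up <- round(spec$upstream_kb * 1000)
  down <- round(spec$downstream_kb * 1000)
  plus <- genes$strand == "+"
  ws <- ifelse(plus, genes$tss - up, genes$tss - down)
  we <- ifelse(plus, genes$tss + down, genes$tss + up)
  ws <- pmax(0, ws)
  we <- pmin(unname(lens[genes$contig]), we)
  we <- pmax(we, ws)
  kb <- (we - ws) / 1000
  counts <- integer(nrow(genes))
  for (ctg in unique(genes$contig)) {
    idx <- which(genes$contig == ctg)
    s <- sort(hits$start[hits$contig == ctg])
    if (length(s)) {
      counts[idx] <- findInterval(we[idx] - 1L, s) -
        findInterval(ws[idx] - 1L, s)
    }
  }
  dens <- counts / kb
  dens[kb <= min_kb] <- NA_real_
  dens
}

#' Mean upstream site density of a gene set
#'
#' Per-gene densities in input order and their unweighted arithmetic mean.
#' Genes whose window clips below 1 kb are excluded (logged); the
#' aggregate definition (total sites / total kb) is available via
#' `mean_type = "aggregate"`.
#'
#' @param genes gene table for the set (non-empty).
#' @param hits sorted hit table.
#' @param spec a [window_spec()].
#' @param genome genome.
#' @param set_id label stored in the result.
#' @param mean_type `"per_gene"` (default) or `"aggregate"`.
#' @param min_kb exclusion threshold for clipped windows, in kb.
#' @return list of class `density_result` with fields set_id, n_genes,
#'   per_gene_density, mean_density, n_excluded.
#' @export
set_mean_density <- function(genes, hits, spec = window_spec(), genome,
                             set_id = "set", mean_type = c("per_gene", "aggregate"),
                             min_kb = 1) {
  mean_type <- match.arg(mean_type)
  if (nrow(genes) == 0L) stop("empty gene set")
  dens <- gene_densities_vec(hits, genes, spec, genome, min_kb = min_kb)
  keep <- !is.na(dens)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message(n_excluded, " gene(s) excluded: window clipped below ", min_kb, " kb")
  }
  if (!any(keep)) stop("all genes excluded by window clipping")
  dens <- dens[keep]
  mean_density <- if (mean_type == "per_gene") {
    mean(dens)
  } else {
    # aggregate: total sites over total kb
    lens <- setNames(Biostrings::width(genome), names(genome))
    gg <- genes[keep, , drop = FALSE]
    tot_sites <- 0; tot_kb <- 0
    for (i in seq_len(nrow(gg))) {
      w <- upstream_window(gg[i, ], spec, lens[[gg$contig[i]]])
      tot_sites <- tot_sites + sites_in_interval(hits, gg$contig[i], w$start, w$end)
      tot_kb <- tot_kb + w$effective_kb
    }
    tot_sites / tot_kb
  }
  structure(list(set_id = set_id, n_genes = sum(keep),
                 per_gene_density = unname(dens),
                 mean_density = mean_density, n_excluded = n_excluded),
            class = "density_result")
}

#' Monte Carlo gene-set enrichment test
#'
#' Tests whether the observed set's mean upstream site density is higher
#' than expected for an equally sized set drawn from a gene pool.  Pool
#' densities are computed once; each permutation draws `n_genes` genes
#' uniformly without replacement from the full pool and records the mean of
#' their precomputed densities.  The empirical p-value is the upper-tail
#' exceedance fraction: `#(perm mean >= observed mean) / n_perm`.
#'
#' @param observed a `density_result` for the observed set.
#' @param pool gene table of the resampling pool (observed genes are not
#'   excluded; plain subsampling).
#' @param hits sorted hit table.
#' @param spec a [window_spec()].
#' @param genome genome.
#' @param n_perm number of permutations (default 1e5).
#' @param seed RNG seed; recorded in the result.
#' @param estimator `"plain"` (exceed/n_perm, flagged `p < 1/n_perm` at zero
#'   exceedances) or `"add_one"` ((exceed+1)/(n_perm+1)).
#' @param min_kb clipped-window exclusion threshold applied to the pool.
#' @return list of class `mc_enrichment_result`.
#' @export
mc_enrichment <- function(observed, pool, hits, spec = window_spec(), genome,
                          n_perm = 1e5, seed,
                          estimator = c("plain", "add_one"), min_kb = 1) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(observed, "density_result"), n_perm >= 1)
  pool_dens <- gene_densities_vec(hits, pool, spec, genome, min_kb = min_kb)
  n_excluded <- sum(is.na(pool_dens))
  if (n_excluded > 0L) {
    message(n_excluded, " pool gene(s) excluded: window clipped below ",
            min_kb, " kb")
  }
  pool_dens <- pool_dens[!is.na(pool_dens)]
  n <- observed$n_genes
  if (n >= length(pool_dens)) stop("set size must be smaller than pool size")
  perm_means <- withr::with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) mean(pool_dens[sample.int(length(pool_dens), n)]),
           numeric(1))
  })
  exceed <- sum(perm_means >= observed$mean_density)
  p <- switch(estimator,
              plain = exceed / n_perm,
              add_one = (exceed + 1) / (n_perm + 1))
  structure(list(set_id = observed$set_id,
                 observed_mean = observed$mean_density,
                 n_genes = n, pool_size = length(pool_dens),
                 n_perm = as.integer(n_perm),
                 exceed_count = as.integer(exceed),
                 p_value = p,
                 p_below_resolution = (estimator == "plain" && exceed == 0L),
                 estimator = estimator, seed = seed,
                 window = unclass(spec)),
            class = "mc_enrichment_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf("Gene-set density '%s': mean %.4f sites/kb over %d genes (%d excluded)\n",
              x$set_id, x$mean_density, x$n_genes, x$n_excluded))
  invisible(x)
}

#' @export
print.mc_enrichment_result <- function(x, ...) {
  p_str <- if (x$p_below_resolution) sprintf("< %g", 1 / x$n_perm)
           else format(x$p_value)
  cat(sprintf(
    "Monte Carlo enrichment '%s': observed mean %.4f sites/kb (n = %d)\n",
    x$set_id, x$observed_mean, x$n_genes))
  cat(sprintf("  pool %d genes, %d permutations, exceedances %d, P %s\n",
              x$pool_size, x$n_perm, x$exceed_count, p_str))
  invisible(x)
}
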