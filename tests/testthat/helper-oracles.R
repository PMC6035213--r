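# Independent brute-force oracles used to validate the package's fast paths.
# These share no code with the implementation: plain string/regex machinery
# and exhaustive loops only.

IUPAC_REGEX <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B")

chr_revcomp <- function(x) {
  paste(rev(COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

iupac_to_regex <- function(pat) {
  paste0("^", paste(IUPAC_REGEX[strsplit(pat, "", fixed = TRUE)[[1]]],
                    collapse = ""), "$")
}

# Exhaustive sliding-window scan: every offset, both strands, on forward
# coordinates.  Returns the same column layout as find_guide_sites().
oracle_scan <- function(genome, guide) {
  L <- nchar(guide$protospacer)
  P <- nchar(guide$pam)
  w <- L + P
  pam_re <- iupac_to_regex(guide$pam)
  rc_pam_re <- iupac_to_regex(chr_revcomp(guide$pam))
  rc_proto <- chr_revcomp(guide$protospacer)
  rows <- list()
  for (ctg in names(genome)) {
    s <- as.character(genome[[ctg]])
    n <- nchar(s)
    if (n < w) next
    off <- seq_len(n - w + 1L)                 # 1-based full-site starts
    frag <- substring(s, off, off + w - 1L)
    plus <- substr(frag, 1L, L) == guide$protospacer &
      grepl(pam_re, substr(frag, L + 1L, w))
    minus <- substr(frag, P + 1L, w) == rc_proto &
      grepl(rc_pam_re, substr(frag, 1L, P))
    if (any(plus)) {
      s0 <- off[plus] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        guide_name = guide$name, contig = ctg, start = s0, end = s0 + L,
        strand = "+", stringsAsFactors = FALSE)
    }
    if (any(minus)) {
      s0 <- off[minus] - 1L + P
      rows[[length(rows) + 1L]] <- data.frame(
        guide_name = guide$name, contig = ctg, start = s0, end = s0 + L,
        strand = "-", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(data.frame(
    guide_name = character(), contig = character(), start = integer(),
    end = integer(), strand = character(), stringsAsFactors = FALSE))))
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact subset-enumeration p-value: all size-n subsets of the pool.
oracle_exact_p <- function(pool_densities, n, observed_mean) {
  subsets <- utils::combn(length(pool_densities), n)
  means <- apply(subsets, 2, function(i) mean(pool_densities[i]))
  mean(means >= observed_mean)
}

# Quadratic brute-force peak/site overlap fraction (>= 1 bp intersection).
oracle_overlap_fraction <- function(peaks, hits) {
  hit_any <- vapply(seq_len(nrow(peaks)), function(i) {
    any(hits$contig == peaks$contig[i] &
          hits$start < peaks$end[i] & hits$end > peaks$start[i])
  }, logical(1))
  sum(hit_any) / nrow(peaks)
}

# Random A/C/G/T string.
random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small synthetic configuration for fast unit tests.
tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_contigs = 2L, contig_length = 300000L,
               pool_size = 50L, enriched_set_size = 6L,
               peaks_per_sample = 100L)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}
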