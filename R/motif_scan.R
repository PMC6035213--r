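#' Scan a genome for guide target sites
#'
#' Exhaustive, strand-aware search for every occurrence of the guide's
#' protospacer immediately followed 3' by a PAM match.  Matching is exact
#' (no mismatches); `N` in the genome matches nothing.  Overlapping
#' occurrences are all reported.
#'
#' Coordinates in the result are 0-based half-open on the forward genomic
#' strand and delimit the protospacer only (the PAM lies at `[end, end+|pam|)`
#' for `+` hits and `[start-|pam|, start)` for `-` hits).
#'
#' @param genome genome (`DNAStringSet`, see [as_genome()]).
#' @param guide a [guide_spec()].
#' @param require_pam when `FALSE` the PAM is not required and hits are bare
#'   protospacer matches (used for census sensitivity checks).
#' @return data.frame with columns guide_name, contig, start, end, strand,
#'   sorted by (contig, start, strand).
#' @export
find_guide_sites <- function(genome, guide, require_pam = TRUE) {
  stopifnot(methods::is(genome, "DNAStringSet"), !is.null(names(genome)),
            inherits(guide, "guide_spec"))
  pam <- if (require_pam) guide$pam else ""
  L <- nchar(guide$protospacer)
  P <- nchar(pam)
  pat_fwd <- Biostrings::DNAString(paste0(guide$protospacer, pam))
  pat_rev <- Biostrings::reverseComplement(pat_fwd)

  per_contig <- lapply(names(genome), function(ctg) {
    subj <- genome[[ctg]]
    rows <- list()
    if (length(subj) >= L + P) {
      mf <- scan_one_strand(pat_fwd, subj)
      mr <- scan_one_strand(pat_rev, subj)
      if (length(mf)) {
        s0 <- BiocGenerics::start(mf) - 1L       # full-match start, 0-based
        rows$f <- data.frame(guide_name = guide$name, contig = ctg,
                             start = s0, end = s0 + L, strand = "+",
                             stringsAsFactors = FALSE)
      }
      if (length(mr)) {
        s0 <- BiocGenerics::start(mr) - 1L
        rows$r <- data.frame(guide_name = guide$name, contig = ctg,
                             start = s0 + P, end = s0 + P + L, strand = "-",
                             stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  })
  hits <- do.call(rbind, c(per_contig, list(empty_hits())))
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# One-strand pattern match dropping any hit whose genomic span contains N:
# Biostrings lets an ambiguity code in the pattern match a literal N in the
# subject, but a site interrupted by N must not count.
scan_one_strand <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, subject, fixed = "subject")
  if (length(m) == 0L) return(m)
  has_n <- Biostrings::alphabetFrequency(m)[, "N"] > 0L
  m[!has_n]
}

empty_hits <- function() {
  data.frame(guide_name = character(), contig = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

#' Genome-wide site census for one guide
#' @inheritParams find_guide_sites
#' @return integer number of sites (both strands).
#' @export
genome_site_count <- function(genome, guide, require_pam = TRUE) {
  nrow(find_guide_sites(genome, guide, require_pam = require_pam))
}

#' Count hits whose protospacer start falls in a window
#'
#' Membership is decided by the protospacer's forward-coordinate start
#' position `s`: counted iff `start <= s < end` on the named contig.
#' Both strands count; overlapping occurrences each count.
#'
#' @param hits sorted hit table from [find_guide_sites()].
#' @param contig contig name.
#' @param start,end 0-based half-open window.
#' @return integer count.
#' @export
sites_in_interval <- function(hits, contig, start, end) {
  stopifnot(start < end)
  assert_hits_sorted(hits)
  sum(hits$contig == contig & hits$start >= start & hits$start < end)
}

assert_hits_sorted <- function(hits) {
  if (nrow(hits) > 1L) {
    o <- order(hits$contig, hits$start, hits$strand)
    if (!identical(o, seq_len(nrow(hits)))) {
      stop("hit table must be sorted by (contig, start, strand); ",
           "pass find_guide_sites() output unmodified", call. = FALSE)
    }
  }
  invisible(hits)
}

#' Export hits as BED6
#'
#' name column carries the guide name, score is 0, strand column is used.
#'
#' @param hits hit table.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$end,
                    hits$guide_name, 0L, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
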