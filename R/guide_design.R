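#' Enumerate candidate protospacers in a query sequence
#'
#' Tiles both strands of a query (e.g. a motif consensus or a promoter
#' window) and reports every position where a `guide_len` protospacer is
#' immediately followed 3' by a PAM match.  Offsets are 0-based starts of
#' the protospacer interval on the forward query coordinates, for both
#' strands (scanner convention).
#'
#' @param query nucleotide string (A/C/G/T/N).
#' @param guide_len protospacer length (>= 10; e.g. 14 for truncated guides).
#' @param pam IUPAC PAM pattern (default "NGG").
#' @param pam_proximal_k how many PAM-proximal bases to record (default 4).
#' @return data.frame of candidates with columns sequence, offset, strand,
#'   pam_observed, pam_proximal, disfavored_count, sorted by offset then
#'   strand; `disfavored_count` is `NA` until [pam_proximal_report()] is
#'   applied.
#' @export
enumerate_protospacers <- function(query, guide_len, pam = "NGG",
                                   pam_proximal_k = 4L) {
  query <- toupper(query)
  assert_nucleotides(query, allow_n = TRUE, what = "query")
  stopifnot(guide_len >= 10L)
  if (nchar(query) < guide_len + nchar(pam)) {
    warning("query shorter than guide length + PAM; no candidates")
    return(empty_candidates())
  }
  g <- as_genome(c(query = query))
  hits <- find_guide_sites_anylen(g, guide_len, pam)
  if (nrow(hits) == 0L) return(empty_candidates())
  seqs <- character(nrow(hits))
  pams <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (hits$strand[i] == "+") {
      seqs[i] <- substr(query, s + 1L, e)
      pams[i] <- substr(query, e + 1L, e + nchar(pam))
    } else {
      seqs[i] <- revcomp(substr(query, s + 1L, e))
      pams[i] <- revcomp(substr(query, s + 1L - nchar(pam), s))
    }
  }
  k <- min(pam_proximal_k, guide_len)
  out <- data.frame(sequence = seqs, offset = hits$start,
                    strand = hits$strand, pam_observed = pams,
                    pam_proximal = substr(seqs, guide_len - k + 1L, guide_len),
                    disfavored_count = NA_integer_,
                    stringsAsFactors = FALSE)
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Site scan for an arbitrary-length window: enumerate candidate positions by
# matching only the PAM pattern, then take the guide_len bases 5' of it.
find_guide_sites_anylen <- function(genome, guide_len, pam) {
  q <- genome[[1]]
  n <- length(q)
  P <- nchar(pam)
  pam_f <- Biostrings::DNAString(pam)
  pam_r <- Biostrings::reverseComplement(pam_f)
  rows <- list()
  mf <- Biostrings::matchPattern(pam_f, q, fixed = "subject")
  if (length(mf)) {
    ps <- BiocGenerics::start(mf) - 1L           # PAM start, 0-based
    keep <- ps - guide_len >= 0L
    ps <- ps[keep]
    if (length(ps)) {
      proto <- substring(as.character(q), ps - guide_len + 1L, ps)
      pamseq <- substring(as.character(q), ps + 1L, ps + P)
      ok <- !grepl("N", proto, fixed = TRUE) & !grepl("N", pamseq, fixed = TRUE)
      rows$f <- data.frame(guide_name = "candidate", contig = names(genome)[1],
                           start = ps[ok] - guide_len, end = ps[ok],
                           strand = "+", stringsAsFactors = FALSE)
    }
  }
  mr <- Biostrings::matchPattern(pam_r, q, fixed = "subject")
  if (length(mr)) {
    pe <- BiocGenerics::end(mr)                  # PAM end, 1-based == 0-based excl
    keep <- pe + guide_len <= n
    pe <- pe[keep]
    if (length(pe)) {
      proto <- substring(as.character(q), pe + 1L, pe + guide_len)
      pamseq <- substring(as.character(q), pe - P + 1L, pe)
      ok <- !grepl("N", proto, fixed = TRUE) & !grepl("N", pamseq, fixed = TRUE)
      rows$r <- data.frame(guide_name = "candidate", contig = names(genome)[1],
                           start = pe[ok], end = pe[ok] + guide_len,
                           strand = "-", stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, c(rows, list(empty_hits())))
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_candidates <- function() {
  data.frame(sequence = character(), offset = integer(), strand = character(),
             pam_observed = character(), pam_proximal = character(),
             disfavored_count = integer(), stringsAsFactors = FALSE)
}

#' Count disfavoured PAM-proximal bases in a candidate
#'
#' Position 1 is the protospacer base adjacent to the PAM, counting away
#' from it.  The disfavoured-base table is configuration, not a shipped
#' default: supply e.g. `list("1" = "T", "2" = c("T", "G"))`.
#'
#' @param candidate one candidate row (or list) with a `sequence` field.
#' @param disfavored_table named list mapping position (as character
#'   `"1"`..`"k"`) to a vector of disfavoured bases; empty list gives 0.
#' @param k number of PAM-proximal positions inspected (default 4).
#' @return integer count of disfavoured positions (`<= k`).
#' @export
pam_proximal_report <- function(candidate, disfavored_table = list(), k = 4L) {
  seq <- candidate$sequence
  stopifnot(k <= nchar(seq))
  if (length(disfavored_table) == 0L) return(0L)
  pos <- as.integer(names(disfavored_table))
  if (anyNA(pos) || any(pos < 1L) || any(pos > k)) {
    stop("disfavored_table keys must be positions in 1..k")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  sum(vapply(pos, function(i) {
    chars[n - i + 1L] %in% disfavored_table[[as.character(i)]]
  }, logical(1)))
}

#' Annotate and rank candidates by disfavoured PAM-proximal content
#'
#' Fills `disfavored_count` for every candidate and sorts ascending by it,
#' ties broken by offset.
#'
#' @param candidates output of [enumerate_protospacers()].
#' @inheritParams pam_proximal_report
#' @return the annotated, ranked candidate table.
#' @export
rank_candidates <- function(candidates, disfavored_table = list(), k = 4L) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates$disfavored_count <- vapply(seq_len(nrow(candidates)), function(i) {
    as.integer(pam_proximal_report(candidates[i, ], disfavored_table, k))
  }, integer(1))
  candidates <- candidates[order(candidates$disfavored_count, candidates$offset), ,
                           drop = FALSE]
  rownames(candidates) <- NULL
  candidates
}
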