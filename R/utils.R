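#' @importFrom stats rpois runif setNames pt var
#' @importFrom utils packageVersion
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse-complement a nucleotide string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()];
#' accepts IUPAC ambiguity codes.
#'
#' @param x single nucleotide string.
#' @return the reverse complement, as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Does concrete base `base` satisfy IUPAC code `code`?  N in the subject
# satisfies nothing (conservative matching).
iupac_base_match <- function(code, base) {
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("unknown IUPAC code: ", code)
  base %in% set
}

# Vectorised: does concrete sequence `seq` (length k string) match IUPAC
# pattern `pat` of the same length?
iupac_match <- function(pat, seq) {
  if (nchar(pat) != nchar(seq)) return(FALSE)
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  sc <- strsplit(seq, "", fixed = TRUE)[[1]]
  all(vapply(seq_along(pc), function(i) iupac_base_match(pc[i], sc[i]), logical(1)))
}

# First concrete base satisfying an IUPAC code (deterministic realisation).
iupac_realize <- function(pat) {
  pc <- strsplit(pat, "", fixed = TRUE)[[1]]
  paste(vapply(pc, function(code) IUPAC_SETS[[code]][1], character(1)), collapse = "")
}

assert_nucleotides <- function(x, allow_n = TRUE, what = "sequence") {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- grepl(sprintf("[^%s]", alphabet), x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {%s}: %s",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ","),
                 x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

# Stream of sub-seeds derived from a master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
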