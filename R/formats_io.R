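#' Build a genome object from named sequences
#'
#' The in-memory genome representation used throughout the package is a
#' named [Biostrings::DNAStringSet]: one entry per contig, sequences
#' uppercased, alphabet restricted to A/C/G/T/N.  All genomic coordinates
#' elsewhere in the package are 0-based half-open (BED convention).
#'
#' @param seqs named character vector (or DNAStringSet) of contig sequences.
#' @return a validated `DNAStringSet`.
#' @export
as_genome <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- toupper(seqs)
    assert_nucleotides(seqs, allow_n = TRUE, what = "contig sequence")
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  validate_genome(seqs)
}

#' @rdname as_genome
#' @param genome a genome object.
#' @export
validate_genome <- function(genome) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm))) stop("contig names must be non-empty")
  if (anyDuplicated(nm)) stop("duplicate contig name: ", nm[duplicated(nm)][1])
  if (any(Biostrings::width(genome) == 0L)) stop("empty contig sequence")
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(freq) - rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) {
    stop("contig ", nm[extra > 0][1], " contains characters outside {A,C,G,T,N}")
  }
  genome
}

#' Total genome length in bp
#' @param genome a genome (`DNAStringSet`).
#' @return integer total length.
#' @export
genome_total_length <- function(genome) sum(Biostrings::width(genome))

#' Read a genome FASTA
#'
#' Header token before the first whitespace becomes the contig name;
#' sequences are uppercased on read.  Characters outside A/C/G/T/N
#' (either case) and duplicate contig names are format errors.
#'
#' @param path FASTA file path.
#' @return genome as a named `DNAStringSet`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("FASTA record '", names(x)[bad][1],
         "' contains characters outside {A,C,G,T,N,a,c,g,t,n}")
  }
  as_genome(setNames(seqs, names(x)))
}

#' Write a genome FASTA
#' @param genome genome object.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  Biostrings::writeXStringSet(validate_genome(genome), path, width = width)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Five tab-separated columns: gene_id, contig, tss, strand, biotype.
#' TSS is a 0-based position.  A header line is auto-detected by a
#' non-integer value in the tss field.
#'
#' @param path TSV path.
#' @param genome optional genome; when given, TSS positions are checked
#'   against contig bounds.
#' @return data.frame with columns gene_id, contig, tss, strand, biotype.
#' @export
read_genes <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty gene annotation file: ", path)
    return(data.frame(gene_id = character(), contig = character(),
                      tss = integer(), strand = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    stop("gene table row ", which(nf < 5L)[1], ": expected 5 tab-separated columns")
  }
  # header detection: tss column not an integer
  if (!grepl("^-?[0-9]+$", fields[[1]][3])) {
    fields <- fields[-1]
    if (length(fields) == 0L) {
      warning("gene annotation file has a header but no records: ", path)
      return(data.frame(gene_id = character(), contig = character(),
                        tss = integer(), strand = character(),
                        biotype = character(), stringsAsFactors = FALSE))
    }
  }
  m <- do.call(rbind, fields)
  genes <- data.frame(gene_id = m[, 1], contig = m[, 2],
                      tss = suppressWarnings(as.integer(m[, 3])),
                      strand = m[, 4], biotype = m[, 5],
                      stringsAsFactors = FALSE)
  if (anyNA(genes$tss)) {
    stop("gene table row ", which(is.na(genes$tss))[1], ": tss is not an integer")
  }
  validate_genes(genes, genome)
}

#' @rdname read_genes
#' @param genes gene data.frame.
#' @export
validate_genes <- function(genes, genome = NULL) {
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad)) stop("gene table row ", which(bad)[1], ": strand must be + or -")
  if (any(genes$tss < 0L)) {
    stop("gene table row ", which(genes$tss < 0L)[1], ": negative tss")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("gene table row ", which(duplicated(genes$gene_id))[1],
         ": duplicate gene_id '", genes$gene_id[duplicated(genes$gene_id)][1], "'")
  }
  if (!is.null(genome)) {
    len <- setNames(Biostrings::width(genome), names(genome))
    miss <- !genes$contig %in% names(len)
    if (any(miss)) stop("gene on unknown contig: ", genes$contig[miss][1])
    oob <- genes$tss >= len[genes$contig]
    if (any(oob)) stop("gene ", genes$gene_id[oob][1], ": tss beyond contig end")
  }
  genes
}

#' @rdname read_genes
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("gene_id", "contig", "tss", "strand", "biotype")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read ATAC-seq peaks from a BED3+ file
#'
#' BED's 0-based half-open convention is preserved unchanged; columns
#' beyond the first three are ignored.
#'
#' @param path BED file path.
#' @param sample_id sample label attached to every record.
#' @return data.frame with columns sample_id, contig, start, end.
#' @export
read_peaks <- function(path, sample_id) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(sample_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("BED row ", which(nf < 3L)[1], ": fewer than 3 columns")
  m <- do.call(rbind, lapply(fields, `[`, 1:3))
  peaks <- data.frame(sample_id = sample_id, contig = m[, 1],
                      start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                      stringsAsFactors = FALSE)
  bad <- peaks$start >= peaks$end
  if (any(bad)) stop("BED row ", which(bad)[1], ": start >= end")
  peaks
}

#' @rdname read_peaks
#' @param peaks peak data.frame for one sample.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(all(peaks$start < peaks$end))
  utils::write.table(peaks[, c("contig", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a guide specification
#'
#' @param name guide name, unique within a guide set.
#' @param protospacer targeting sequence, A/C/G/T only, length >= 10.
#' @param pam IUPAC pattern immediately 3' of the protospacer
#'   (default "NGG", the SpCas9 PAM).
#' @return list of class `guide_spec`.
#' @export
guide_spec <- function(name, protospacer, pam = "NGG") {
  protospacer <- toupper(protospacer)
  pam <- toupper(pam)
  stopifnot(nzchar(name), nzchar(pam))
  if (nchar(protospacer) < 10L) stop("protospacer shorter than 10 nt: ", name)
  if (grepl("[^ACGT]", protospacer)) {
    stop("guide '", name, "': protospacer must contain only A,C,G,T (no N)")
  }
  if (grepl(sprintf("[^%s]", paste(names(IUPAC_SETS), collapse = "")), pam)) {
    stop("guide '", name, "': PAM contains a non-IUPAC character")
  }
  structure(list(name = name, protospacer = protospacer, pam = pam),
            class = "guide_spec")
}

#' Read guide specifications from a TSV
#'
#' Columns: name, protospacer, pam (third column optional; default NGG).
#'
#' @param path TSV path.
#' @return list of `guide_spec`.
#' @export
read_guides <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty guide file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1]][1]) == "name") fields <- fields[-1]
  guides <- lapply(fields, function(f) {
    guide_spec(f[1], f[2], if (length(f) >= 3L && nzchar(f[3])) f[3] else "NGG")
  })
  nms <- vapply(guides, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate guide name: ", nms[duplicated(nms)][1])
  guides
}

#' @rdname read_guides
#' @param guides list of `guide_spec`.
#' @export
write_guides <- function(guides, path) {
  if (inherits(guides, "guide_spec")) guides <- list(guides)
  df <- data.frame(name = vapply(guides, `[[`, character(1), "name"),
                   protospacer = vapply(guides, `[[`, character(1), "protospacer"),
                   pam = vapply(guides, `[[`, character(1), "pam"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-set membership list (one gene id per line)
#' @param path text file path.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- readLines(path)
  ids <- trimws(ids[nzchar(trimws(ids))])
  if (anyDuplicated(ids)) stop("duplicate gene id in set: ", ids[duplicated(ids)][1])
  ids
}

#' @importFrom methods is
NULL
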