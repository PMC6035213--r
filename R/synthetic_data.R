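#' Synthetic dataset configuration
#'
#' Defaults encode the study conditions the statistics are validated
#' against: a 2,000-gene protein-coding pool with background upstream site
#' density 0.215 sites/kb, an 18-gene enriched set at 0.409 sites/kb, a
#' -10 kb/+1 kb TSS window, a 14-nt guide with an NGG PAM, and ATAC-style
#' peak sets of 1,000 peaks/sample with site-bearing probabilities 0.008
#' (3 control samples) and 0.019 (5 treated samples).
#'
#' @param seed master RNG seed for the dataset.
#' @param n_contigs,contig_length genome shape; the contigs must jointly
#'   host `pool_size` non-overlapping TSS windows.
#' @param gc_content genome GC fraction (default 0.41, human-like).
#' @param pool_size number of protein-coding pool genes.
#' @param enriched_set_size size of the designated enriched set.
#' @param background_density,enriched_density planted upstream site
#'   densities, sites/kb.
#' @param guide [guide_spec()] whose protospacer+PAM is planted.
#' @param window [window_spec()].
#' @param peaks_per_sample,n_control_samples,n_treated_samples peak-set shape.
#' @param control_overlap_fraction,treated_overlap_fraction per-peak
#'   site-bearing probabilities by group.
#' @param peak_width fixed peak width, bp (default 400, typical ATAC).
#' @param pam_realized concrete PAM written for planted sites (default:
#'   first concrete realisation of the guide's PAM pattern, "AGG" for NGG).
#' @param sanitize destroy accidental guide sites in the background so
#'   scanner output equals planted truth exactly.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_contigs = 4L,
                         contig_length = 5600000L,
                         gc_content = 0.41,
                         pool_size = 2000L,
                         enriched_set_size = 18L,
                         background_density = 0.215,
                         enriched_density = 0.409,
                         guide = guide_spec("g1", "TCATGCTACGATCA", "NGG"),
                         window = window_spec(10, 1),
                         peaks_per_sample = 1000L,
                         n_control_samples = 3L,
                         n_treated_samples = 5L,
                         control_overlap_fraction = 0.008,
                         treated_overlap_fraction = 0.019,
                         peak_width = 400L,
                         pam_realized = NULL,
                         sanitize = TRUE) {
  stopifnot(gc_content > 0, gc_content < 1,
            background_density >= 0, enriched_density >= 0,
            enriched_set_size < pool_size,
            control_overlap_fraction >= 0, control_overlap_fraction <= 1,
            treated_overlap_fraction >= 0, treated_overlap_fraction <= 1,
            inherits(guide, "guide_spec"), inherits(window, "window_spec"))
  span <- round((window$upstream_kb + window$downstream_kb) * 1000)
  if (n_contigs * (contig_length %/% span) < pool_size) {
    stop("contigs too short to host ", pool_size,
         " non-overlapping ", span, "-bp windows; increase contig_length")
  }
  if (is.null(pam_realized)) pam_realized <- iupac_realize(guide$pam)
  if (!iupac_match(guide$pam, pam_realized)) {
    stop("pam_realized does not match the guide's PAM pattern")
  }
  structure(list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
                 contig_length = as.integer(contig_length),
                 gc_content = gc_content, pool_size = as.integer(pool_size),
                 enriched_set_size = as.integer(enriched_set_size),
                 background_density = background_density,
                 enriched_density = enriched_density,
                 guide = guide, window = window,
                 peaks_per_sample = as.integer(peaks_per_sample),
                 n_control_samples = as.integer(n_control_samples),
                 n_treated_samples = as.integer(n_treated_samples),
                 control_overlap_fraction = control_overlap_fraction,
                 treated_overlap_fraction = treated_overlap_fraction,
                 peak_width = as.integer(peak_width),
                 pam_realized = pam_realized,
                 sanitize = isTRUE(sanitize)),
            class = "synth_config")
}

#' Load a synthetic-data configuration from YAML
#'
#' Scalar fields override [synth_config()] defaults; `guide` may be given
#' as a mapping with name/protospacer/pam, `window` as
#' upstream_kb/downstream_kb.
#'
#' @param path YAML file.
#' @return `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$guide)) {
    y$guide <- guide_spec(y$guide$name, y$guide$protospacer,
                          y$guide$pam %||% "NGG")
  }
  if (!is.null(y$window)) {
    y$window <- window_spec(y$window$upstream_kb %||% 10,
                            y$window$downstream_kb %||% 1)
  }
  do.call(synth_config, y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

RAW_BASES <- charToRaw("ACGT")

# i.i.d. base sampling as a raw vector (fast path for Mb-scale contigs).
# GC is realised through a 1000-slot lookup table, so the target fraction
# is honoured to 3 decimals.
sample_bases_raw <- function(n, gc) {
  n_gc <- round(1000 * gc)
  counts <- c(round((1000 - n_gc) / 2), floor(n_gc / 2), ceiling(n_gc / 2))
  counts <- c(counts, 1000 - sum(counts))            # A, C, G, T
  lookup <- rep(RAW_BASES, times = counts)
  lookup[sample.int(1000L, n, replace = TRUE)]
}

#' Generate a guide-site-free background genome
#'
#' i.i.d. bases at the configured GC content.  With `sanitize = TRUE`
#' every accidental occurrence of the guide's protospacer+PAM (either
#' strand) is destroyed by resampling one protospacer base, iterating
#' until the scanner finds zero hits.
#'
#' @param config a [synth_config()].
#' @return genome (`DNAStringSet`).
#' @export
generate_background <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, {
    seqs <- vapply(seq_len(config$n_contigs), function(i) {
      rawToChar(sample_bases_raw(config$contig_length, config$gc_content))
    }, character(1))
    # bases come straight from RAW_BASES; skip re-validation of Mb-scale strings
    genome <- Biostrings::DNAStringSet(setNames(seqs, paste0("chr", seq_len(config$n_contigs))))
    if (config$sanitize) genome <- sanitize_genome(genome, config)$genome
    genome
  })
}

# Destroy guide-site occurrences, optionally sparing planted intervals.
# `spare` is a per-contig list of sorted occupied intervals (0-based
# half-open matrices with columns start,end) that must not be edited; a
# hit identical to a planted site is left alone.
sanitize_genome <- function(genome, config, spare = NULL, truth_hits = NULL,
                            max_iter = 100L) {
  L <- nchar(config$guide$protospacer)
  P <- nchar(config$guide$pam)
  for (iter in seq_len(max_iter)) {
    full_hits <- find_guide_sites(genome, config$guide)
    hits <- if (is.null(truth_hits)) full_hits
            else anti_join_hits(full_hits, truth_hits)
    if (nrow(hits) == 0L) return(list(genome = genome, hits = full_hits))
    seqs <- as.character(genome)
    for (i in seq_len(nrow(hits))) {
      ctg <- hits$contig[i]
      # occupied span incl. PAM, 0-based half-open
      if (hits$strand[i] == "+") {
        span <- c(hits$start[i], hits$end[i] + P)
      } else {
        span <- c(hits$start[i] - P, hits$end[i])
      }
      cand <- setdiff(seq.int(span[1], span[2] - 1L), spare_positions(spare, ctg, span))
      if (length(cand) == 0L) next  # entirely inside planted sites; cannot edit
      pos <- cand[sample.int(length(cand), 1L)]
      old <- substr(seqs[[ctg]], pos + 1L, pos + 1L)
      new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      substr(seqs[[ctg]], pos + 1L, pos + 1L) <- new
    }
    genome <- Biostrings::DNAStringSet(seqs)
  }
  stop("sanitization did not converge in ", max_iter,
       " iterations (pathological guide sequence)")
}

spare_positions <- function(spare, ctg, span) {
  iv <- spare[[ctg]]
  if (is.null(iv) || nrow(iv) == 0L) return(integer())
  sel <- iv[, 2] > span[1] & iv[, 1] < span[2]
  if (!any(sel)) return(integer())
  unlist(lapply(which(sel), function(j) {
    seq.int(max(iv[j, 1], span[1]), min(iv[j, 2], span[2]) - 1L)
  }))
}

anti_join_hits <- function(hits, truth_hits) {
  key <- function(h) paste(h$contig, h$start, h$strand)
  hits[!key(hits) %in% key(truth_hits), , drop = FALSE]
}

#' Plant guide sites in TSS windows at controlled densities
#'
#' Places `pool_size` TSSs with non-overlapping windows (random strands),
#' designates an enriched subset, draws each gene's site count from
#' Poisson(density x effective window kb) — `enriched_density` for set
#' members, `background_density` otherwise — and writes protospacer+PAM
#' copies at uniform non-overlapping positions inside the window, each on
#' a random strand.  With `sanitize = TRUE` the emitted genome is
#' re-sanitised around the planted sites so the scanner recovers exactly
#' the planted truth.
#'
#' Extra designated sets with their own planting rates (e.g. a 13-gene set
#' at 0.280/kb) can be supplied via `extra_sets`.
#'
#' @param genome background genome from [generate_background()].
#' @param config a [synth_config()].
#' @param extra_sets optional list of `list(size =, density =)` planted in
#'   addition to (and disjoint from) the enriched set.
#' @return list with elements `genome`, `genes` (pool annotation),
#'   `hits` (the scanner's output on the emitted genome, produced during
#'   the verification pass; `NULL` when `sanitize = FALSE`) and `truth`
#'   (planted_sites, enriched_gene_ids, extra_set_ids,
#'   per_gene_planted_count).
#' @export
plant_gene_sites <- function(genome, config, extra_sets = NULL) {
  stopifnot(inherits(config, "synth_config"))
  span <- round((config$window$upstream_kb + config$window$downstream_kb) * 1000)
  up <- round(config$window$upstream_kb * 1000)
  down <- round(config$window$downstream_kb * 1000)
  L <- nchar(config$guide$protospacer)
  P <- nchar(config$pam_realized)
  w_site <- L + P
  lens <- Biostrings::width(genome)

  withr::with_seed(config$seed + 1L, {
    # window slots across contigs, in order
    slots <- do.call(rbind, lapply(seq_along(genome), function(ci) {
      k <- lens[ci] %/% span
      if (k == 0L) return(NULL)
      data.frame(contig = names(genome)[ci],
                 slot_start = span * (seq_len(k) - 1L))
    }))
    if (nrow(slots) < config$pool_size) {
      stop("window placement impossible: only ", nrow(slots), " slots for ",
           config$pool_size, " genes; increase contig_length")
    }
    slots <- slots[seq_len(config$pool_size), , drop = FALSE]
    strand <- sample(c("+", "-"), config$pool_size, replace = TRUE)
    tss <- ifelse(strand == "+", slots$slot_start + up, slots$slot_start + down)
    genes <- data.frame(gene_id = sprintf("g%05d", seq_len(config$pool_size)),
                        contig = slots$contig, tss = as.integer(tss),
                        strand = strand, biotype = "protein_coding",
                        stringsAsFactors = FALSE)

    # designate disjoint sets
    avail <- seq_len(config$pool_size)
    enr_idx <- sort(sample(avail, config$enriched_set_size))
    avail <- setdiff(avail, enr_idx)
    extra_idx <- list()
    for (s in seq_along(extra_sets)) {
      idx <- sort(sample(avail, extra_sets[[s]]$size))
      avail <- setdiff(avail, idx)
      extra_idx[[s]] <- idx
    }
    dens <- rep(config$background_density, config$pool_size)
    dens[enr_idx] <- config$enriched_density
    for (s in seq_along(extra_sets)) dens[extra_idx[[s]]] <- extra_sets[[s]]$density

    # per-gene site counts and placements
    win_start <- slots$slot_start
    win_kb <- span / 1000
    counts <- rpois(config$pool_size, dens * win_kb)
    motif_f <- paste0(config$guide$protospacer, config$pam_realized)
    motif_r <- revcomp(motif_f)
    raw_f <- charToRaw(motif_f)
    raw_r <- charToRaw(motif_r)

    seqs_raw <- lapply(seq_along(genome), function(ci) {
      charToRaw(as.character(genome[[ci]]))
    })
    names(seqs_raw) <- names(genome)

    n_tot <- sum(counts)
    p_ctg <- character(n_tot); p_strand <- character(n_tot)
    p_full <- integer(n_tot); p_gene <- character(n_tot)
    at <- 0L
    for (gi in seq_len(config$pool_size)) {
      k <- counts[gi]
      if (k == 0L) next
      starts <- sample_nonoverlapping(win_start[gi], win_start[gi] + span,
                                      w_site, k)
      if (is.null(starts)) {
        stop("window placement impossible: cannot fit ", k,
             " non-overlapping sites in one window")
      }
      site_strand <- sample(c("+", "-"), k, replace = TRUE)
      ctg <- genes$contig[gi]
      for (j in seq_len(k)) {
        s <- starts[j]
        seqs_raw[[ctg]][(s + 1L):(s + w_site)] <-
          if (site_strand[j] == "+") raw_f else raw_r
      }
      idx <- at + seq_len(k)
      p_ctg[idx] <- ctg; p_strand[idx] <- site_strand
      p_full[idx] <- starts; p_gene[idx] <- genes$gene_id[gi]
      at <- at + k
    }
    proto_start <- ifelse(p_strand == "+", p_full, p_full + P)
    planted <- data.frame(guide_name = rep(config$guide$name, n_tot),
                          contig = p_ctg,
                          start = as.integer(proto_start),
                          end = as.integer(proto_start + L),
                          strand = p_strand, gene_id = p_gene,
                          full_start = p_full,
                          full_end = as.integer(p_full + w_site),
                          stringsAsFactors = FALSE)
    genome2 <- Biostrings::DNAStringSet(setNames(vapply(seqs_raw, rawToChar, character(1)),
                                  names(seqs_raw)))

    verified_hits <- NULL
    if (config$sanitize) {
      if (nrow(planted) > 0L) {
        # junction-induced spurious occurrences: resample a base outside all
        # planted spans
        spare <- lapply(names(genome2), function(ctg) {
          iv <- planted[planted$contig == ctg, c("full_start", "full_end"),
                        drop = FALSE]
          as.matrix(iv)
        })
        names(spare) <- names(genome2)
        truth_hits <- planted[, c("contig", "start", "strand")]
        san <- sanitize_genome(genome2, config, spare = spare,
                               truth_hits = truth_hits)
        genome2 <- san$genome
        verified_hits <- san$hits
      } else {
        verified_hits <- find_guide_sites(genome2, config$guide)
      }
    }

    per_gene <- setNames(integer(config$pool_size), genes$gene_id)
    if (nrow(planted) > 0L) {
      tab <- table(planted$gene_id)
      per_gene[names(tab)] <- as.integer(tab)
    }
    ord <- order(planted$contig, planted$start, planted$strand)
    planted <- planted[ord, , drop = FALSE]
    rownames(planted) <- NULL
    list(genome = genome2, genes = genes, hits = verified_hits,
         truth = list(planted_sites = planted,
                      enriched_gene_ids = genes$gene_id[enr_idx],
                      extra_set_ids = lapply(extra_idx, function(i) genes$gene_id[i]),
                      per_gene_planted_count = per_gene))
  })
}

# k non-overlapping starts of width-w sites, uniform in [lo, hi); NULL if
# rejection sampling cannot fit them.
sample_nonoverlapping <- function(lo, hi, w, k, max_tries = 1000L) {
  starts <- integer(0)
  for (tries in seq_len(max_tries)) {
    s <- lo + sample.int(hi - lo - w + 1L, 1L) - 1L
    if (!any(abs(starts - s) < w)) {
      starts <- c(starts, s)
      if (length(starts) == k) return(sort(starts))
    }
  }
  NULL
}

#' Generate per-sample peak sets with controlled site-bearing fractions
#'
#' Each of `peaks_per_sample` peaks is independently site-bearing with its
#' group's overlap probability.  Site-bearing peaks are centred on a
#' uniformly chosen planted site (guaranteeing overlap for
#' `peak_width >= protospacer length`); the rest are placed at positions
#' verified free of planted sites.
#'
#' @param genome planted genome.
#' @param truth truth record from [plant_gene_sites()].
#' @param config a [synth_config()].
#' @return list with `peaks_by_sample` (named list of peak tables),
#'   `groups` (named sample -> group vector) and `truth` updated with
#'   `per_sample_site_bearing_peaks`.
#' @export
generate_peaks <- function(genome, truth, config) {
  stopifnot(inherits(config, "synth_config"))
  sites <- truth$planted_sites
  lens <- setNames(Biostrings::width(genome), names(genome))
  w <- config$peak_width
  samples <- c(
    setNames(rep("control", config$n_control_samples),
             sprintf("ctrl_%d", seq_len(config$n_control_samples))),
    setNames(rep("treated", config$n_treated_samples),
             sprintf("treated_%d", seq_len(config$n_treated_samples))))
  frac <- c(control = config$control_overlap_fraction,
            treated = config$treated_overlap_fraction)
  need_sites <- any(frac[samples] > 0)
  if (need_sites && nrow(sites) == 0L) {
    stop("no planted sites available for site-bearing peaks")
  }
  site_by_contig <- split(sites$start, sites$contig)
  site_by_contig <- lapply(site_by_contig, sort)

  withr::with_seed(config$seed + 2L, {
    per_sample <- list()
    bearing_counts <- setNames(integer(length(samples)), names(samples))
    for (sid in names(samples)) {
      p <- frac[[samples[[sid]]]]
      bearing <- runif(config$peaks_per_sample) < p
      n_bear <- sum(bearing)
      rows <- vector("list", config$peaks_per_sample)
      if (n_bear > 0L) {
        pick <- sample.int(nrow(sites), n_bear, replace = TRUE)
        mid <- (sites$start[pick] + sites$end[pick]) %/% 2L
        start <- mid - w %/% 2L
        ctg <- sites$contig[pick]
        start <- pmax(0L, pmin(start, lens[ctg] - w))
        ok <- start <= sites$start[pick] & start + w >= sites$end[pick] |
              (start < sites$end[pick] & start + w > sites$start[pick])
        if (!all(ok)) stop("peak width too small to overlap a planted site")
        bear_df <- data.frame(sample_id = sid, contig = ctg,
                              start = as.integer(start),
                              end = as.integer(start + w),
                              stringsAsFactors = FALSE)
      } else {
        bear_df <- NULL
      }
      n_free <- config$peaks_per_sample - n_bear
      free_df <- if (n_free > 0L) {
        place_site_free_peaks(n_free, lens, w, site_by_contig, sid)
      }
      df <- rbind(bear_df, free_df)
      rownames(df) <- NULL
      per_sample[[sid]] <- df
      bearing_counts[[sid]] <- n_bear
    }
    truth$per_sample_site_bearing_peaks <- as.list(bearing_counts)
    list(peaks_by_sample = per_sample, groups = samples, truth = truth)
  })
}

place_site_free_peaks <- function(n, lens, w, site_by_contig, sid,
                                  max_tries = 10000L) {
  ctgs <- names(lens)
  out_ctg <- character(n); out_start <- integer(n)
  placed <- 0L
  for (tries in seq_len(max_tries + n)) {
    ctg <- sample(ctgs, 1L, prob = lens)
    s <- sample.int(lens[[ctg]] - w + 1L, 1L) - 1L
    starts <- site_by_contig[[ctg]]
    # protospacer intervals are short; overlap iff some site start in
    # (s - site_len, s + w); site length bounded by w assumption -> use
    # conservative window of w on both sides
    if (!is.null(starts) && length(starts)) {
      lo <- findInterval(s - w, starts)
      hi <- findInterval(s + w, starts)
      nearby <- if (hi > lo) starts[(lo + 1L):hi] else integer()
      if (length(nearby) && any(nearby < s + w & nearby + w > s)) next
    }
    placed <- placed + 1L
    out_ctg[placed] <- ctg; out_start[placed] <- s
    if (placed == n) break
  }
  if (placed < n) stop("could not place ", n, " site-free peaks; ",
                       "insufficient site-free space")
  data.frame(sample_id = sid, contig = out_ctg, start = out_start,
             end = out_start + w, stringsAsFactors = FALSE)
}
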