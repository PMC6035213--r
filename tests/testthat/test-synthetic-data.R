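test_that("sanitized backgrounds contain zero guide sites and are reproducible", {
  cfg <- tiny_config(seed = 5, n_contigs = 1L, contig_length = 100000L,
                     pool_size = 9L, enriched_set_size = 2L)
  g <- generate_background(cfg)
  expect_equal(genome_site_count(g, cfg$guide), 0L)
  g2 <- generate_background(cfg)
  expect_identical(as.character(g), as.character(g2))
  g3 <- generate_background(tiny_config(seed = 6, n_contigs = 1L,
                                        contig_length = 100000L,
                                        pool_size = 9L, enriched_set_size = 2L))
  expect_false(identical(as.character(g), as.character(g3)))
})

test_that("background GC content is within a 3-SE binomial band", {
  cfg <- tiny_config(seed = 10, n_contigs = 1L, contig_length = 1000000L,
                     pool_size = 9L, enriched_set_size = 2L, gc_content = 0.5,
                     sanitize = FALSE)
  g <- generate_background(cfg)
  freq <- Biostrings::alphabetFrequency(g[[1]])
  gc <- sum(freq[c("C", "G")]) / sum(freq[c("A", "C", "G", "T")])
  se <- sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(gc - 0.5), 3 * se)
})

test_that("zero densities plant zero sites", {
  cfg <- tiny_config(seed = 14, background_density = 0, enriched_density = 0)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  expect_equal(nrow(pl$truth$planted_sites), 0L)
  expect_true(all(unlist(pl$truth$per_gene_planted_count) == 0L))
  expect_equal(nrow(pl$hits), 0L)
})

test_that("scanner-recovered sites equal planted truth exactly under sanitize", {
  cfg <- tiny_config(seed = 23)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- find_guide_sites(pl$genome, cfg$guide)
  truth <- pl$truth$planted_sites
  expect_equal(hits$contig, truth$contig)
  expect_equal(hits$start, truth$start)
  expect_equal(hits$end, truth$end)
  expect_equal(hits$strand, truth$strand)
  expect_identical(hits, pl$hits)
  # per-gene recount through the window machinery matches recorded truth
  dens <- guidesites:::gene_densities_vec(hits, pl$genes, cfg$window,
                                          pl$genome, min_kb = 0)
  span_kb <- cfg$window$upstream_kb + cfg$window$downstream_kb
  counts <- as.integer(round(dens * span_kb))
  expect_equal(counts,
               unname(unlist(pl$truth$per_gene_planted_count[pl$genes$gene_id])))
})

test_that("gene windows are disjoint, strand-mirrored and inside contigs", {
  cfg <- tiny_config(seed = 37)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  lens <- setNames(Biostrings::width(pl$genome), names(pl$genome))
  wins <- lapply(seq_len(nrow(pl$genes)), function(i) {
    w <- upstream_window(pl$genes[i, ], cfg$window, lens[[pl$genes$contig[i]]])
    c(start = w$start, end = w$end, kb = w$effective_kb)
  })
  wins <- do.call(rbind, wins)
  expect_true(all(wins[, "kb"] == 11))
  for (ctg in unique(pl$genes$contig)) {
    w <- wins[pl$genes$contig == ctg, , drop = FALSE]
    w <- w[order(w[, "start"]), , drop = FALSE]
    expect_true(all(w[-1, "start"] >= w[-nrow(w), "end"]))
    expect_true(all(w[, "end"] <= lens[[ctg]]))
  }
})

test_that("extra gene sets are disjoint and planted at their own rates", {
  cfg <- tiny_config(seed = 41, pool_size = 120L, contig_length = 700000L,
                     enriched_set_size = 10L, background_density = 0,
                     enriched_density = 1)
  extra <- list(list(size = 8, density = 2))
  pl <- plant_gene_sites(generate_background(cfg), cfg, extra_sets = extra)
  enr <- pl$truth$enriched_gene_ids
  ex <- pl$truth$extra_set_ids[[1]]
  expect_length(intersect(enr, ex), 0L)
  counts <- unlist(pl$truth$per_gene_planted_count)
  bg_genes <- setdiff(pl$genes$gene_id, c(enr, ex))
  expect_true(all(counts[bg_genes] == 0L))
  # planted counts are Poisson draws around density * 11 kb
  expect_gt(mean(counts[ex]), mean(counts[enr]))
})

test_that("per-gene planted counts follow Poisson(density x window kb)", {
  lambda <- 0.215 * 11
  counts <- integer()
  for (seed in 1:6) {
    cfg <- tiny_config(seed = seed, pool_size = 50L,
                       enriched_set_size = 1L,
                       enriched_density = 0.215)
    pl <- plant_gene_sites(generate_background(cfg), cfg)
    counts <- c(counts, unlist(pl$truth$per_gene_planted_count))
  }
  # chi-square GOF with pooled upper tail
  breaks <- 0:6
  obs <- c(vapply(breaks, function(k) sum(counts == k), numeric(1)),
           sum(counts > max(breaks)))
  prob <- c(dpois(breaks, lambda), ppois(max(breaks), lambda, lower.tail = FALSE))
  chisq <- suppressWarnings(chisq.test(obs, p = prob))
  expect_gt(chisq$p.value, 0.01)
})

test_that("set mean density recovers the planted enrichment rate across seeds", {
  # desk-scale replicate of the parameter-recovery design: 6 enriched genes
  # at 0.409/kb, pool at 0.215/kb, averaged over seeds
  means <- vapply(1:12, function(seed) {
    cfg <- tiny_config(seed = 100 + seed)
    pl <- plant_gene_sites(generate_background(cfg), cfg)
    obs <- pl$genes[pl$genes$gene_id %in% pl$truth$enriched_gene_ids, ]
    set_mean_density(obs, pl$hits, cfg$window, pl$genome)$mean_density
  }, numeric(1))
  # SE of the mean over 12 seeds of 6-gene sets ~ 0.023; allow 3 SE
  expect_lt(abs(mean(means) - 0.409), 0.07)
})

test_that("zero overlap fractions produce entirely site-free peak sets", {
  cfg <- tiny_config(seed = 3, control_overlap_fraction = 0,
                     treated_overlap_fraction = 0, peaks_per_sample = 80L)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  pk <- generate_peaks(pl$genome, pl$truth, cfg)
  for (sid in names(pk$peaks_by_sample)) {
    expect_equal(sample_overlap_fraction(pk$peaks_by_sample[[sid]], pl$hits), 0)
  }
  expect_true(all(unlist(pk$truth$per_sample_site_bearing_peaks) == 0L))
})

test_that("realized per-sample fractions equal truth counts / peaks exactly", {
  cfg <- tiny_config(seed = 47, control_overlap_fraction = 0.05,
                     treated_overlap_fraction = 0.12, peaks_per_sample = 200L)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  pk <- generate_peaks(pl$genome, pl$truth, cfg)
  hits <- find_guide_sites(pl$genome, cfg$guide)
  for (sid in names(pk$peaks_by_sample)) {
    f <- sample_overlap_fraction(pk$peaks_by_sample[[sid]], hits)
    expect_equal(f, pk$truth$per_sample_site_bearing_peaks[[sid]] / 200)
  }
  # peaks stay inside contig bounds
  lens <- setNames(Biostrings::width(pl$genome), names(pl$genome))
  for (p in pk$peaks_by_sample) {
    expect_true(all(p$start >= 0L))
    expect_true(all(p$end <= lens[p$contig]))
    expect_true(all(p$end - p$start == cfg$peak_width))
  }
})

test_that("generate_peaks fails cleanly when site-bearing peaks are impossible", {
  cfg <- tiny_config(seed = 2, background_density = 0, enriched_density = 0,
                     control_overlap_fraction = 0.5,
                     treated_overlap_fraction = 0.5, peaks_per_sample = 40L)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  expect_error(generate_peaks(pl$genome, pl$truth, cfg), "no planted sites")
})

test_that("config validation rejects impossible geometries and set sizes", {
  expect_error(synth_config(pool_size = 100L, n_contigs = 1L,
                            contig_length = 50000L), "contigs too short")
  expect_error(tiny_config(enriched_set_size = 50L), "enriched_set_size")
  expect_error(tiny_config(gc_content = 0), "gc_content")
})

test_that("YAML configs round-trip into synth_config", {
  path <- withr::local_tempfile(fileext = ".yaml", lines = c(
    "seed: 9", "n_contigs: 1", "contig_length: 200000", "pool_size: 12",
    "enriched_set_size: 3", "gc_content: 0.45",
    "guide:", "  name: gX", "  protospacer: TTGCAATGCCAGTA",
    "window:", "  upstream_kb: 10", "  downstream_kb: 1"))
  cfg <- read_synth_config(path)
  expect_s3_class(cfg, "synth_config")
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$guide$name, "gX")
  expect_equal(cfg$guide$pam, "NGG")
  expect_equal(cfg$window$upstream_kb, 10)
})
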