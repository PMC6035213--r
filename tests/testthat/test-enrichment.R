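test_that("upstream_window anchors at the TSS, mirrors by strand and clips", {
  spec <- window_spec(10, 1)
  w <- upstream_window(list(tss = 50000L, strand = "+"), spec, 100000L)
  expect_equal(c(w$start, w$end), c(40000, 51000))
  expect_equal(w$effective_kb, 11)

  wm <- upstream_window(list(tss = 50000L, strand = "-"), spec, 100000L)
  expect_equal(c(wm$start, wm$end), c(49000, 60000))
  expect_equal(wm$effective_kb, 11)

  wc <- upstream_window(list(tss = 500L, strand = "+"), spec, 100000L)
  expect_equal(c(wc$start, wc$end), c(0, 1500))
  expect_equal(wc$effective_kb, 1.5)
})

make_planted_window_genome <- function(n_sites, seed = 17) {
  # 100-kb contig; gene at tss 50000 (+); sites planted inside [40000, 51000)
  guide <- guide_spec("g1", "TCATGCTACGATCA", "NGG")
  set.seed(seed)
  seq <- random_seq(100000)
  starts <- if (n_sites > 0) seq(40100, by = 900, length.out = n_sites) else integer()
  for (s in starts) substr(seq, s + 1, s + 17) <- "TCATGCTACGATCAAGG"
  g <- as_genome(c(c1 = seq))
  gene <- data.frame(gene_id = "gene1", contig = "c1", tss = 50000L,
                     strand = "+", biotype = "protein_coding")
  list(genome = g, gene = gene, guide = guide)
}

test_that("gene_density is sites per effective kb", {
  d0 <- make_planted_window_genome(0)
  hits0 <- find_guide_sites(d0$genome, d0$guide)
  expect_equal(gene_density(hits0, d0$gene, window_spec(), d0$genome), 0)

  d11 <- make_planted_window_genome(11)
  hits11 <- find_guide_sites(d11$genome, d11$guide)
  expect_equal(gene_density(hits11, d11$gene, window_spec(), d11$genome), 1)
})

test_that("gene_density equals a brute-force recount on random plantings", {
  d <- make_planted_window_genome(7, seed = 23)
  hits <- find_guide_sites(d$genome, d$guide)
  w <- upstream_window(d$gene, window_spec(), 100000L)
  naive <- sum(hits$start >= w$start & hits$start < w$end) / w$effective_kb
  expect_equal(gene_density(hits, d$gene, window_spec(), d$genome), naive)
})

test_that("a zero-length clipped window excludes the gene with a warning", {
  g <- as_genome(c(c1 = random_seq(2000, seed = 2)))
  gene <- data.frame(gene_id = "edge", contig = "c1", tss = 0L,
                     strand = "-", biotype = "pc")
  hits <- find_guide_sites(g, guide_spec("g1", "TCATGCTACGATCA"))
  # minus-strand window is [tss-1000, tss+10000) -> clipped [0, 2000); fine
  expect_gte(gene_density(hits, gene, window_spec(), g), 0)
  gene_plus <- data.frame(gene_id = "edge2", contig = "c1", tss = 0L,
                          strand = "+", biotype = "pc")
  # plus-strand window [tss-10000, tss+1000) has positive width; shrink
  # downstream to force a zero-width window
  expect_warning(
    d <- gene_density(hits, gene_plus, window_spec(10, 0), g),
    "excluded")
  expect_true(is.na(d))
})

test_that("set_mean_density is the unweighted mean, in input order", {
  cfg <- tiny_config(seed = 41)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  one <- pl$genes[3, , drop = FALSE]
  r1 <- set_mean_density(one, hits, cfg$window, pl$genome)
  expect_equal(r1$n_genes, 1L)
  expect_equal(r1$mean_density, r1$per_gene_density[1])

  sub <- pl$genes[c(10, 2, 30), ]
  r <- set_mean_density(sub, hits, cfg$window, pl$genome, set_id = "sub")
  expect_equal(r$per_gene_density,
               vapply(c(10, 2, 30), function(i) {
                 gene_density(hits, pl$genes[i, ], cfg$window, pl$genome)
               }, numeric(1)))
  expect_equal(r$mean_density, mean(r$per_gene_density))
  expect_error(set_mean_density(pl$genes[0, ], hits, cfg$window, pl$genome),
               "empty")
})

test_that("vectorised pool densities equal per-gene recomputation", {
  cfg <- tiny_config(seed = 13)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  fast <- guidesites:::gene_densities_vec(hits, pl$genes, cfg$window,
                                          pl$genome, min_kb = 0)
  slow <- vapply(seq_len(nrow(pl$genes)), function(i) {
    gene_density(hits, pl$genes[i, ], cfg$window, pl$genome)
  }, numeric(1))
  expect_equal(fast, slow)
})

test_that("a homogeneous pool gives p = 1", {
  cfg <- tiny_config(seed = 3, background_density = 0, enriched_density = 0)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  obs_genes <- pl$genes[pl$genes$gene_id %in% pl$truth$enriched_gene_ids, ]
  obs <- set_mean_density(obs_genes, hits, cfg$window, pl$genome)
  mc <- mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                      n_perm = 500, seed = 8)
  expect_equal(mc$p_value, 1)
  expect_equal(mc$exceed_count, 500L)
})

test_that("Monte Carlo p matches exact subset enumeration on a 5-gene pool", {
  # pool densities {0,0,0,1,1}; observed pair with mean 1 -> exact p = 1/10
  guide <- guide_spec("g1", "TCATGCTACGATCA", "NGG")
  set.seed(19)
  seq <- random_seq(60000)
  # five genes, 11-kb windows tiling [0, 55000); plant 11 sites (density 1)
  # in windows of genes 4 and 5
  for (w in 3:4) {
    for (s in seq(w * 11000 + 50, by = 990, length.out = 11)) {
      substr(seq, s + 1, s + 17) <- "TCATGCTACGATCAAGG"
    }
  }
  g <- as_genome(c(c1 = seq))
  genes <- data.frame(gene_id = paste0("g", 1:5), contig = "c1",
                      tss = as.integer(seq(0, 4) * 11000 + 10000),
                      strand = "+", biotype = "pc")
  hits <- find_guide_sites(g, guide)
  pool_dens <- guidesites:::gene_densities_vec(hits, genes, window_spec(), g)
  expect_equal(sort(round(pool_dens, 6)), c(0, 0, 0, 1, 1))

  obs <- set_mean_density(genes[4:5, ], hits, window_spec(), g)
  expect_equal(obs$mean_density, 1)
  exact <- oracle_exact_p(pool_dens, 2, obs$mean_density)
  expect_equal(exact, 0.1)

  n_perm <- 1e5
  mc <- mc_enrichment(obs, genes, hits, window_spec(), g,
                      n_perm = n_perm, seed = 4)
  se <- sqrt(exact * (1 - exact) / n_perm)
  expect_lt(abs(mc$p_value - exact), 3 * se)
})

test_that("exceed_count is monotone non-increasing in the observed mean", {
  cfg <- tiny_config(seed = 29)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  obs_genes <- pl$genes[1:8, ]
  obs <- set_mean_density(obs_genes, hits, cfg$window, pl$genome)
  counts <- vapply(c(0, 0.1, 0.2, 0.3, 0.5), function(m) {
    fake <- obs
    fake$mean_density <- m
    mc_enrichment(fake, pl$genes, hits, cfg$window, pl$genome,
                  n_perm = 300, seed = 77)$exceed_count
  }, integer(1))
  expect_false(is.unsorted(rev(counts)))
})

test_that("null p-values are approximately uniform for pool-resampled sets", {
  cfg <- tiny_config(seed = 55, pool_size = 80, contig_length = 500000L)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  pool_dens <- guidesites:::gene_densities_vec(hits, pl$genes, cfg$window,
                                               pl$genome, min_kb = 1)
  n_perm <- 1000
  set.seed(99)
  pvals <- replicate(200, {
    idx <- sample.int(length(pool_dens), 10)
    obs <- structure(list(set_id = "null", n_genes = 10L,
                          per_gene_density = pool_dens[idx],
                          mean_density = mean(pool_dens[idx]),
                          n_excluded = 0L), class = "density_result")
    mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                  n_perm = n_perm, seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("zero exceedances are flagged as below resolution and add-one works", {
  cfg <- tiny_config(seed = 61)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  obs <- set_mean_density(pl$genes[1:5, ], hits, cfg$window, pl$genome)
  obs$mean_density <- 1e6  # unreachable by any permutation
  mc <- mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                      n_perm = 200, seed = 5)
  expect_equal(mc$p_value, 0)
  expect_true(mc$p_below_resolution)
  mc1 <- mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                       n_perm = 200, seed = 5, estimator = "add_one")
  expect_equal(mc1$p_value, 1 / 201)
  expect_false(mc1$p_below_resolution)
})

test_that("mc_enrichment is reproducible from its seed and validates sizes", {
  cfg <- tiny_config(seed = 71)
  pl <- plant_gene_sites(generate_background(cfg), cfg)
  hits <- pl$hits
  obs <- set_mean_density(pl$genes[1:6, ], hits, cfg$window, pl$genome)
  a <- mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                     n_perm = 400, seed = 123)
  b <- mc_enrichment(obs, pl$genes, hits, cfg$window, pl$genome,
                     n_perm = 400, seed = 123)
  expect_identical(a, b)
  big <- obs
  big$n_genes <- nrow(pl$genes)
  expect_error(mc_enrichment(big, pl$genes, hits, cfg$window, pl$genome,
                             n_perm = 10, seed = 1), "pool size")
})
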