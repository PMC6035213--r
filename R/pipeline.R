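#' Run manifest for machine-readable reports
#'
#' Records the command, package version, seed and an md5 digest of every
#' input file, for embedding in JSON reports.
#'
#' @param command short command label.
#' @param inputs character vector of input file paths.
#' @param seed seed used, or NA.
#' @return named list.
#' @export
run_manifest <- function(command, inputs = character(), seed = NA_integer_) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(command = command,
       tool_version = as.character(packageVersion("guidesites")),
       seed = seed,
       input_md5 = digests,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a result object to JSON with an embedded manifest
#'
#' The result payload is seed-deterministic; the manifest (which carries a
#' timestamp) is attached under its own key so payloads can be compared
#' byte-for-byte across runs.
#'
#' @param result list-like result (density/enrichment/overlap result).
#' @param path output JSON path.
#' @param manifest optional [run_manifest()].
#' @return `path`, invisibly.
#' @export
write_result_json <- function(result, path, manifest = NULL) {
  payload <- unclass(result)
  out <- if (is.null(manifest)) list(result = payload)
         else list(result = payload, manifest = manifest)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Generate and write a complete synthetic dataset
#'
#' Runs [generate_background()], [plant_gene_sites()] and
#' [generate_peaks()], then writes genome.fa, genes.tsv, enriched_set.txt,
#' guides.tsv, one peaks_<sample>.bed per sample, sample_sheet.tsv and
#' truth.json under `outdir`.
#'
#' @param config a [synth_config()].
#' @param outdir output directory (created if missing).
#' @param extra_sets passed to [plant_gene_sites()].
#' @return invisibly, a list with the in-memory objects (genome, genes,
#'   truth, peaks_by_sample, groups) and file paths.
#' @export
simulate_dataset <- function(config, outdir, extra_sets = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_background(config)
  planted <- plant_gene_sites(genome, config, extra_sets = extra_sets)
  pk <- generate_peaks(planted$genome, planted$truth, config)
  paths <- list(
    genome = file.path(outdir, "genome.fa"),
    genes = file.path(outdir, "genes.tsv"),
    enriched_set = file.path(outdir, "enriched_set.txt"),
    guides = file.path(outdir, "guides.tsv"),
    sample_sheet = file.path(outdir, "sample_sheet.tsv"),
    truth = file.path(outdir, "truth.json"))
  write_fasta(planted$genome, paths$genome)
  write_genes(planted$genes, paths$genes)
  writeLines(pk$truth$enriched_gene_ids, paths$enriched_set)
  write_guides(list(config$guide), paths$guides)
  sheet <- data.frame(sample_id = names(pk$groups),
                      path = sprintf("peaks_%s.bed", names(pk$groups)),
                      group = unname(pk$groups))
  for (sid in names(pk$peaks_by_sample)) {
    write_peaks(pk$peaks_by_sample[[sid]],
                file.path(outdir, sprintf("peaks_%s.bed", sid)))
  }
  utils::write.table(sheet, paths$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  truth_json <- pk$truth
  truth_json$planted_sites <- truth_json$planted_sites[
    , c("guide_name", "contig", "start", "end", "strand", "gene_id")]
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(list(genome = planted$genome, genes = planted$genes,
                   truth = pk$truth, peaks_by_sample = pk$peaks_by_sample,
                   groups = pk$groups), paths = list(paths)))
}

#' Scan, density and Monte Carlo enrichment in one call
#'
#' Scans the genome for the guide's sites, computes the observed set's
#' mean upstream density and tests it against the pool by Monte Carlo
#' subsampling.
#'
#' @param genome genome.
#' @param genes pool gene table (the resampling pool).
#' @param guide a [guide_spec()].
#' @param set_ids gene ids of the observed set (must all be in `genes`).
#' @param window a [window_spec()].
#' @param n_perm permutations (default 1e5).
#' @param seed RNG seed.
#' @param hits optional precomputed hit table (skips the scan).
#' @return `mc_enrichment_result`.
#' @export
run_enrichment <- function(genome, genes, guide, set_ids,
                           window = window_spec(), n_perm = 1e5, seed = 1L,
                           hits = NULL) {
  missing <- setdiff(set_ids, genes$gene_id)
  if (length(missing)) {
    stop("set gene(s) absent from pool annotation: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(hits)) hits <- find_guide_sites(genome, guide)
  set_genes <- genes[match(set_ids, genes$gene_id), , drop = FALSE]
  obs <- set_mean_density(set_genes, hits, window, genome, set_id = "observed")
  mc_enrichment(obs, genes, hits, window, genome, n_perm = n_perm, seed = seed)
}

#' Peak/site overlap comparison from a sample sheet
#'
#' @param genome genome.
#' @param guide a [guide_spec()].
#' @param sample_sheet data.frame with columns sample_id, path, group
#'   (control/treated); paths resolved relative to `dir`.
#' @param dir directory containing the BED files.
#' @param hits optional precomputed hit table.
#' @return `overlap_comparison`.
#' @export
run_peak_overlap <- function(genome, guide, sample_sheet, dir = ".",
                             hits = NULL) {
  need <- c("sample_id", "path", "group")
  stopifnot(all(need %in% names(sample_sheet)))
  n_per_group <- table(sample_sheet$group)
  if (any(n_per_group < 2L)) {
    stop("need >= 2 samples per group; got ",
         paste(sprintf("%s=%d", names(n_per_group), n_per_group), collapse = ", "))
  }
  if (is.null(hits)) hits <- find_guide_sites(genome, guide)
  peaks <- lapply(seq_len(nrow(sample_sheet)), function(i) {
    read_peaks(file.path(dir, sample_sheet$path[i]), sample_sheet$sample_id[i])
  })
  names(peaks) <- sample_sheet$sample_id
  groups <- setNames(sample_sheet$group, sample_sheet$sample_id)
  overlap_comparison(peaks, groups, hits)
}
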