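#' Fraction of peaks containing a guide site
#'
#' A peak counts (once, regardless of how many sites it holds) when its
#' interval intersects a hit's protospacer interval by at least 1 bp on the
#' same contig.  `mode = "within"` instead requires the full protospacer
#' inside the peak.
#'
#' @param peaks peak table for one sample (non-empty).
#' @param hits sorted hit table.
#' @param mode `"any"` (>= 1 bp intersection, default) or `"within"`.
#' @return fraction in `[0, 1]`.
#' @export
sample_overlap_fraction <- function(peaks, hits, mode = c("any", "within")) {
  mode <- match.arg(mode)
  if (nrow(peaks) == 0L) stop("empty peak list: overlap fraction undefined")
  assert_hits_sorted(hits)
  n_olap <- 0L
  for (ctg in unique(peaks$contig)) {
    p <- peaks[peaks$contig == ctg, , drop = FALSE]
    h <- hits[hits$contig == ctg, , drop = FALSE]
    if (nrow(h) == 0L) next
    # 0-based half-open -> 1-based closed for IRanges
    pr <- IRanges::IRanges(start = p$start + 1L, end = p$end)
    hr <- IRanges::IRanges(start = h$start + 1L, end = h$end)
    cnt <- switch(mode,
      any = IRanges::countOverlaps(pr, hr, minoverlap = 1L),
      within = IRanges::countOverlaps(hr, pr, type = "within"))
    if (mode == "within") {
      # count peaks that fully contain >= 1 hit
      ov <- IRanges::findOverlaps(hr, pr, type = "within")
      n_olap <- n_olap + length(unique(S4Vectors::subjectHits(ov)))
    } else {
      n_olap <- n_olap + sum(cnt > 0L)
    }
  }
  n_olap / nrow(peaks)
}

#' Two-group comparison of peak overlap fractions
#'
#' Classical pooled-variance two-sample two-tailed Student's t-test on the
#' per-sample fractions, compared untransformed.  Degenerate cases: zero
#' pooled variance with equal means gives `p = 1`; zero pooled variance
#' with unequal means gives `p = 0` with `p_below_machine = TRUE`.
#'
#' @param fractions_control,fractions_treated per-sample overlap fractions
#'   (each length >= 2).
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return list of class `overlap_comparison` with group means, t statistic,
#'   degrees of freedom and two-tailed p-value.
#' @export
compare_groups <- function(fractions_control, fractions_treated, welch = FALSE) {
  n1 <- length(fractions_control); n2 <- length(fractions_treated)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group for a t-test")
  m1 <- mean(fractions_control); m2 <- mean(fractions_treated)
  v1 <- var(fractions_control); v2 <- var(fractions_treated)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- n1 + n2 - 2
  }
  p_below_machine <- FALSE
  if (se2 == 0) {
    if (m1 == m2) { t_stat <- 0; p <- 1 }
    else { t_stat <- sign(m2 - m1) * Inf; p <- 0; p_below_machine <- TRUE }
  } else {
    t_stat <- (m2 - m1) / sqrt(se2)
    p <- 2 * pt(-abs(t_stat), df)
  }
  structure(list(mean_control = m1, mean_treated = m2,
                 n_control = n1, n_treated = n2,
                 t_statistic = t_stat, df = df, p_value = p,
                 p_below_machine = p_below_machine,
                 test = if (welch) "welch" else "pooled"),
            class = "overlap_comparison")
}

#' Peak/site overlap comparison across a sample sheet
#'
#' Computes each sample's overlap fraction and runs [compare_groups()]
#' between the `control` and `treated` groups.
#'
#' @param peaks_by_sample named list of per-sample peak tables.
#' @param groups named character vector mapping sample_id to
#'   `"control"`/`"treated"`.
#' @param hits sorted hit table.
#' @param mode overlap mode, see [sample_overlap_fraction()].
#' @return `overlap_comparison` with an added `per_sample_fraction` field.
#' @export
overlap_comparison <- function(peaks_by_sample, groups, hits,
                               mode = c("any", "within")) {
  mode <- match.arg(mode)
  stopifnot(all(names(peaks_by_sample) %in% names(groups)))
  fr <- vapply(peaks_by_sample, sample_overlap_fraction,
               numeric(1), hits = hits, mode = mode)
  grp <- groups[names(fr)]
  bad <- !grp %in% c("control", "treated")
  if (any(bad)) stop("unknown group label: ", grp[bad][1])
  res <- compare_groups(fr[grp == "control"], fr[grp == "treated"])
  res$per_sample_fraction <- fr
  res$group_assignment <- grp
  res
}

#' @export
print.overlap_comparison <- function(x, ...) {
  cat(sprintf(
    "Peak overlap: control %.2f%% (n = %d) vs treated %.2f%% (n = %d)\n",
    100 * x$mean_control, x$n_control, 100 * x$mean_treated, x$n_treated))
  cat(sprintf("  %s t = %.3f, df = %.3g, two-tailed P = %.4g\n",
              x$test, x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' @importFrom S4Vectors subjectHits
NULL
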