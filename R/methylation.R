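# Per-exon CpG methylation and group comparisons -----------------------------

#' Average CpG methylation per exon
#'
#' Collapses strand pairs of a CpG (a minus-strand record at position p+1 is
#' averaged with the plus-strand record at p) and computes the unweighted
#' mean percent methylation of the CpGs inside each exon with coverage at
#' least `min_coverage`. Coverage does not weight the mean. Exons with no
#' covered CpG are excluded; their count is attached as attribute
#' `n_excluded`.
#'
#' @param exons data.frame with `chrom`, `start`, `end`, `strand` and any id
#'   columns (e.g. `gene_id`, `exon_rank`).
#' @param methylation_records data.frame from [read_bedmethyl()].
#' @param min_coverage minimum per-record read coverage (default 1).
#' @return data.frame of exons with `n_cpgs` and `mean_percent`.
#' @export
exon_methylation <- function(exons, methylation_records, min_coverage = 1L) {
  ex <- data.table::as.data.table(exons)
  mr <- data.table::as.data.table(methylation_records)
  mr <- mr[coverage >= min_coverage]
  if (!"strand" %in% names(mr)) mr[, strand := "+"]
  # collapse the two strands of one CpG onto the plus-strand C position
  mr[, cpg_pos := ifelse(strand == "-", position - 1L, position)]
  site <- mr[, .(percent = mean(percent_methylated)), by = .(chrom, cpg_pos)]

  ex[, exon_idx := .I]
  eg <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  sg <- GenomicRanges::GRanges(site$chrom, IRanges::IRanges(site$cpg_pos, site$cpg_pos))
  ov <- GenomicRanges::findOverlaps(sg, eg, ignore.strand = TRUE)
  hits <- data.table::data.table(exon_idx = S4Vectors::subjectHits(ov),
                                 percent = site$percent[S4Vectors::queryHits(ov)])
  agg <- hits[, .(n_cpgs = .N, mean_percent = mean(percent)), by = exon_idx]
  out <- merge(ex, agg, by = "exon_idx")
  n_excluded <- nrow(ex) - nrow(out)
  out[, exon_idx := NULL]
  res <- data.table::setDF(out)
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Compare exon methylation between groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on per-exon mean methylation,
#' plus per-group ECDF points. Groups with fewer than 3 exons are skipped
#' with a note.
#'
#' @param exon_meth data.frame from [exon_methylation()].
#' @param grouping vector of group labels, one per row of `exon_meth` (or the
#'   name of a column in it).
#' @return list with `tests` (`group_a`, `group_b`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `p_value`, `note`) and `ecdf` (per group:
#'   `percent`, `F`).
#' @export
compare_methylation_groups <- function(exon_meth, grouping) {
  g <- if (length(grouping) == 1L && is.character(grouping) &&
           grouping %in% names(exon_meth)) exon_meth[[grouping]] else grouping
  stopifnot(length(g) == nrow(exon_meth))
  x <- exon_meth$mean_percent
  groups <- sort(unique(as.character(g)))
  if (length(groups) < 2L) stop("need at least two groups")
  combos <- utils::combn(groups, 2L)
  tests <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1L, i]; b <- combos[2L, i]
    xa <- x[g == a]; xb <- x[g == b]
    if (length(xa) < 3L || length(xb) < 3L) {
      return(data.frame(group_a = a, group_b = b, n_a = length(xa), n_b = length(xb),
                        mean_a = mean(xa), mean_b = mean(xb), p_value = NA_real_,
                        note = "skipped: group n < 3", stringsAsFactors = FALSE))
    }
    p <- if (length(unique(c(xa, xb))) == 1L) 1.0 else
      suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
    data.frame(group_a = a, group_b = b, n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), mean_b = mean(xb), p_value = p, note = "",
               stringsAsFactors = FALSE)
  })
  ecdf_pts <- lapply(groups, function(gr) {
    v <- sort(x[g == gr])
    if (length(v) == 0L) return(NULL)
    data.frame(group = gr, percent = v, F = seq_along(v) / length(v),
               stringsAsFactors = FALSE)
  })
  list(tests = do.call(rbind, tests), ecdf = do.call(rbind, ecdf_pts))
}
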