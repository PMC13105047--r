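# Constitutive-intron extraction and recursive-junction classification ------

#' Extract constitutive introns from an annotation
#'
#' An intron interval is kept only if (a) every transcript of its gene whose
#' range spans the interval contains the intron with identical coordinates
#' (no annotated alternative usage), and (b) it overlaps no other distinct
#' intron interval anywhere in the annotation. Intervals are deduplicated by
#' (chrom, start, end, strand).
#'
#' @param annotation a [genome_annotation()].
#' @param ignore_strand_overlap if `TRUE` (default) rule (b) also discards
#'   introns overlapping an intron on the opposite strand.
#' @param alt_isoform_rule apply rule (a) (default `TRUE`).
#' @return data.frame of introns with `position_class` (transcription order)
#'   and `length`.
#' @export
extract_constitutive_introns <- function(annotation, ignore_strand_overlap = TRUE,
                                         alt_isoform_rule = TRUE) {
  stopifnot(inherits(annotation, "genome_annotation"))
  intr <- data.table::as.data.table(annotation$introns)
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), gene_id = character(0),
                      transcript_id = character(0), intron_rank = integer(0),
                      position_class = character(0), length = integer(0))
  if (nrow(intr) == 0L) return(empty)
  intr[, key := paste(chrom, start, end, strand, sep = ":")]

  keep_key <- unique(intr$key)
  if (alt_isoform_rule) {
    ex <- data.table::as.data.table(annotation$exons)
    tx <- ex[, .(tx_start = min(start), tx_end = max(end), gene_id = gene_id[1L]),
             by = transcript_id]
    uint <- unique(intr[, .(key, chrom, start, end, strand, gene_id)])
    n_exact <- intr[, .(n_exact = data.table::uniqueN(transcript_id)), by = key]
    uint <- merge(uint, n_exact, by = "key")
    # transcripts of the same gene whose range spans the intron interval
    spans <- merge(uint[, .(key, gene_id, start, end)], tx,
                   by = "gene_id", allow.cartesian = TRUE)
    n_span <- spans[tx_start <= start & tx_end >= end, .(n_span = .N), by = key]
    uint <- merge(uint, n_span, by = "key", all.x = TRUE)
    keep_key <- uint[n_exact == n_span]$key
  }

  uall <- unique(intr[, .(key, chrom, start, end, strand)])
  gr <- GenomicRanges::GRanges(uall$chrom, IRanges::IRanges(uall$start, uall$end),
                               strand = uall$strand)
  ov <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = ignore_strand_overlap)
  ov <- ov[S4Vectors::queryHits(ov) != S4Vectors::subjectHits(ov)]
  overlapped <- uall$key[unique(S4Vectors::queryHits(ov))]
  keep_key <- setdiff(keep_key, overlapped)

  out <- intr[key %in% keep_key]
  # one row per interval; representative transcript = first in transcript order
  data.table::setorder(out, chrom, start, end, strand, transcript_id)
  out <- out[, .SD[1L], by = key]
  res <- data.table::setDF(out[, .(chrom, start, end, strand, gene_id, transcript_id,
                                   intron_rank, position_class, length)])
  res
}

# strand-aware boundary comparison of one junction against one host intron;
# vectorized over pairs. Returns class, recursive-site coordinates and the
# distances of each recursive site to BOTH annotated sites.
compare_boundaries <- function(js, je, is, ie, strand) {
  plus <- strand == "+"
  exact <- js == is & je == ie
  # transcription-orientation: does the junction 5' boundary sit strictly
  # inside (downstream of the annotated 5'SS), does the 3' boundary sit
  # strictly inside (upstream of the annotated 3'SS)?
  rec5_in <- ifelse(plus, js > is, je < ie)
  rec3_in <- ifelse(plus, je < ie, js > is)
  anchor5 <- ifelse(plus, js, je)   # genomic coordinate of the junction 5' boundary
  anchor3 <- ifelse(plus, je, js)
  cls <- ifelse(exact, "basic",
         ifelse(rec5_in & rec3_in, "nested",
         ifelse(rec5_in, "RS5",
         ifelse(rec3_in, "RS3", "invalid"))))
  d5 <- ifelse(rec5_in & !exact, pmin(abs(anchor5 - is), abs(anchor5 - ie)), NA_real_)
  d3 <- ifelse(rec3_in & !exact, pmin(abs(anchor3 - is), abs(anchor3 - ie)), NA_real_)
  list(class = cls,
       rec5 = ifelse(!exact & rec5_in, anchor5, NA_real_),
       rec3 = ifelse(!exact & rec3_in, anchor3, NA_real_),
       d5 = d5, d3 = d3)
}

#' Classify nascent splice junctions against constitutive introns
#'
#' Junctions are aggregated per (chrom, start, end, strand) within each phase
#' (unique reads summed over samples), filtered at `min_unique_reads`, and
#' candidate recursive junctions are restricted to those absent from every
#' mature table at any read depth. Each junction contained in a constitutive
#' intron on the same strand is classified by strand-aware boundary
#' comparison: both boundaries annotated = basic evidence; a recursive
#' boundary on the 5' and/or 3' side = RS5 / RS3 / nested. Recursive sites
#' closer than `min_rs_distance` to either annotated splice site, RS-class
#' host introns shorter than `min_rs_intron_length`, and basic introns
#' shorter than `min_basic_length` are discarded.
#'
#' @param introns constitutive introns from [extract_constitutive_introns()].
#' @param nascent_junctions,mature_junctions junction data.frames (or lists
#'   of them) as returned by [read_sj_table()].
#' @param min_unique_reads read-support threshold (default 3).
#' @param min_rs_distance minimum distance of a recursive site from both
#'   annotated splice sites (default 75).
#' @param min_rs_intron_length minimum host-intron length for RS classes
#'   (default 150).
#' @param min_basic_length minimum intron length for basic evidence
#'   (default 75).
#' @return list with `introns` (one row per (intron, RS class) observed,
#'   with recursive-site coordinates of the best-supported junction),
#'   `junctions` (per-junction assignments) and `discarded` (junctions with
#'   a discard reason).
#' @export
classify_junctions <- function(introns, nascent_junctions, mature_junctions,
                               min_unique_reads = 3L, min_rs_distance = 75L,
                               min_rs_intron_length = 150L, min_basic_length = 75L) {
  bindj <- function(x) {
    if (is.data.frame(x)) data.table::as.data.table(x)
    else data.table::rbindlist(x, use.names = TRUE)
  }
  nas <- bindj(nascent_junctions)
  mat <- bindj(mature_junctions)
  intr <- data.table::as.data.table(introns)
  intr[, intron_id := paste(chrom, start, end, strand, sep = ":")]

  discards <- list()
  if (nrow(nas) > 0L) {
    unk <- nas$strand == "*"
    if (any(unk)) {
      discards$strand <- cbind(nas[unk], reason = "strand_unknown")
      nas <- nas[!unk]
    }
  }
  # sum unique reads over samples of the same phase, then threshold
  agg <- nas[, .(unique_reads = sum(unique_reads)), by = .(chrom, start, end, strand)]
  low <- agg$unique_reads < min_unique_reads
  if (any(low)) discards$low <- cbind(agg[low], reason = "below_min_reads")
  agg <- agg[!low]
  mature_keys <- if (nrow(mat) > 0L) unique(junction_key(mat)) else character(0)
  agg[, key := junction_key(agg)]
  agg[, in_mature := key %in% mature_keys]

  jgr <- GenomicRanges::GRanges(agg$chrom, IRanges::IRanges(agg$start, agg$end),
                                strand = agg$strand)
  igr <- GenomicRanges::GRanges(intr$chrom, IRanges::IRanges(intr$start, intr$end),
                                strand = intr$strand)
  ov <- GenomicRanges::findOverlaps(jgr, igr, type = "within", ignore.strand = FALSE)
  hit <- unique(S4Vectors::queryHits(ov))
  if (length(hit) < nrow(agg)) {
    discards$orphan <- cbind(agg[setdiff(seq_len(nrow(agg)), hit),
                                 .(chrom, start, end, strand, unique_reads)],
                             reason = "no_constitutive_intron")
  }

  pairs <- data.table::data.table(j = S4Vectors::queryHits(ov), i = S4Vectors::subjectHits(ov))
  out_junc <- data.table::data.table()
  if (nrow(pairs) > 0L) {
    pj <- agg[pairs$j]
    pi <- intr[pairs$i]
    cb <- compare_boundaries(pj$start, pj$end, pi$start, pi$end, pi$strand)
    res <- data.table::data.table(
      intron_id = pi$intron_id, chrom = pj$chrom, start = pj$start, end = pj$end,
      strand = pj$strand, unique_reads = pj$unique_reads, in_mature = pj$in_mature,
      rs_class = cb$class, recursive_5ss = cb$rec5, recursive_3ss = cb$rec3,
      d5 = cb$d5, d3 = cb$d3,
      intron_length = pi$end - pi$start + 1L)
    is_rs <- res$rs_class %in% c("RS5", "RS3", "nested")
    reason <- rep(NA_character_, nrow(res))
    reason[is_rs & res$in_mature] <- "present_in_mature"
    reason[is_rs & is.na(reason) & res$intron_length < min_rs_intron_length] <- "host_intron_too_short"
    too_close <- is_rs & is.na(reason) &
      ((!is.na(res$d5) & res$d5 < min_rs_distance) |
       (!is.na(res$d3) & res$d3 < min_rs_distance))
    reason[too_close] <- "recursive_site_too_close"
    reason[res$rs_class == "basic" & res$intron_length < min_basic_length] <- "basic_intron_too_short"
    reason[res$rs_class == "invalid"] <- "boundary_mismatch"
    if (any(!is.na(reason))) {
      discards$rules <- cbind(res[!is.na(reason), .(chrom, start, end, strand, unique_reads)],
                              reason = reason[!is.na(reason)])
    }
    out_junc <- res[is.na(reason)]
  }

  cls_rows <- data.table::data.table()
  if (nrow(out_junc) > 0L) {
    best <- out_junc[order(-unique_reads, start, end),
                     .(recursive_5ss = recursive_5ss[1L], recursive_3ss = recursive_3ss[1L],
                       n_junctions = .N, total_unique_reads = sum(unique_reads)),
                     by = .(intron_id, rs_class)]
    cls_rows <- merge(intr, best, by = "intron_id")
    # an intron with RS evidence is reported per RS class; basic evidence is
    # reported only when the intron carries no RS-class junction
    rs_ids <- unique(cls_rows[rs_class != "basic"]$intron_id)
    cls_rows <- cls_rows[rs_class != "basic" | !(intron_id %in% rs_ids)]
    stopifnot(all(cls_rows[rs_class != "basic"]$length >= min_rs_intron_length))
    dd <- cls_rows[rs_class %in% c("RS5", "nested")]
    if (nrow(dd) > 0L) {
      stopifnot(all(pmin(abs(dd$recursive_5ss - dd$start),
                         abs(dd$recursive_5ss - dd$end)) >= min_rs_distance))
    }
    dd <- cls_rows[rs_class %in% c("RS3", "nested")]
    if (nrow(dd) > 0L) {
      stopifnot(all(pmin(abs(dd$recursive_3ss - dd$start),
                         abs(dd$recursive_3ss - dd$end)) >= min_rs_distance))
    }
  }
  disc <- if (length(discards) > 0L) {
    data.table::rbindlist(lapply(discards, function(d)
      d[, intersect(c("chrom", "start", "end", "strand", "unique_reads", "reason"),
                    names(d)), with = FALSE]), fill = TRUE)
  } else data.table::data.table(chrom = character(0), start = integer(0),
                                end = integer(0), strand = character(0),
                                unique_reads = integer(0), reason = character(0))
  list(introns = data.table::setDF(cls_rows),
       junctions = data.table::setDF(out_junc),
       discarded = data.table::setDF(disc))
}

#' Summarize junction lengths and intron-position usage per RS class
#'
#' @param classified result of [classify_junctions()].
#' @param junctions optional combined junction table (with `phase`) used for
#'   the per-phase length summary of exact (basic) junctions; the nascent
#'   classified junctions are always summarized.
#' @return list with `lengths` (per class and phase: count, mean, median
#'   junction length) and `positions` (per class: fraction of introns
#'   occurring as first/middle/last).
#' @export
junction_length_summary <- function(classified, junctions = NULL) {
  jc <- data.table::as.data.table(classified$junctions)
  lens <- data.table::data.table()
  if (nrow(jc) > 0L) {
    lens <- jc[, .(phase = "nascent", n = .N,
                   mean_length = mean(end - start + 1),
                   median_length = stats::median(end - start + 1)), by = rs_class]
  }
  if (!is.null(junctions)) {
    jx <- data.table::as.data.table(junctions)
    ik <- unique(data.table::as.data.table(classified$introns)[, paste(chrom, start, end, strand, sep = ":")])
    jx <- jx[junction_key(jx) %in% ik]
    if (nrow(jx) > 0L) {
      ph <- jx[, .(rs_class = "basic", n = .N,
                   mean_length = mean(end - start + 1),
                   median_length = stats::median(end - start + 1)), by = phase]
      lens <- rbind(lens, ph[, .(rs_class, phase, n, mean_length, median_length)],
                    use.names = TRUE, fill = TRUE)
    }
  }
  ci <- data.table::as.data.table(classified$introns)
  pos <- data.table::data.table()
  if (nrow(ci) > 0L) {
    pos <- ci[, {
      tt <- table(factor(position_class, levels = c("first", "middle", "last")))
      list(n = .N, first_fraction = unname(tt["first"]) / .N,
           middle_fraction = unname(tt["middle"]) / .N,
           last_fraction = unname(tt["last"]) / .N)
    }, by = rs_class]
  }
  list(lengths = data.table::setDF(lens), positions = data.table::setDF(pos))
}

#' AGGU/C ratchet-motif fraction at recursive sites
#'
#' For each RS class and site type, the fraction of recursive sites whose
#' sense-strand tetramer across the junction boundary (last two bases of the
#' removed segment followed by the first two of the retained one) matches
#' AGG\[T/C\] (AGGU/C in RNA). Sites too close to a contig edge are excluded
#' and counted.
#'
#' @param classified result of [classify_junctions()].
#' @param genome DNAStringSet.
#' @return data.frame with `rs_class`, `site_type`, `n_sites`, `n_edge_excluded`,
#'   `aggu_fraction` (NA for empty classes).
#' @export
motif_at_recursive_sites <- function(classified, genome) {
  jc <- data.table::as.data.table(classified$junctions)
  jc <- jc[rs_class %in% c("RS5", "RS3", "nested")]
  grid <- data.table::CJ(rs_class = c("RS5", "RS3", "nested"),
                         site_type = c("recursive5", "recursive3"))
  grid <- grid[(site_type == "recursive5" & rs_class %in% c("RS5", "nested")) |
               (site_type == "recursive3" & rs_class %in% c("RS3", "nested"))]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cls <- grid$rs_class[i]; st <- grid$site_type[i]
    sub <- jc[rs_class == cls]
    if (st == "recursive5") {
      sub <- sub[!is.na(recursive_5ss)]
      # window -2..+1 anchored on the first retained base
      seqs <- if (nrow(sub) > 0L) extract_window(genome, sub$chrom, sub$recursive_5ss,
                                                 sub$strand, c(-2L, 1L)) else character(0)
    } else {
      sub <- sub[!is.na(recursive_3ss)]
      # window -1..+2 anchored on the last removed base
      seqs <- if (nrow(sub) > 0L) extract_window(genome, sub$chrom, sub$recursive_3ss,
                                                 sub$strand, c(-1L, 2L)) else character(0)
    }
    n_edge <- sum(is.na(seqs))
    seqs <- seqs[!is.na(seqs)]
    data.frame(rs_class = cls, site_type = st, n_sites = length(seqs),
               n_edge_excluded = n_edge,
               aggu_fraction = if (length(seqs) == 0L) NA_real_
                               else mean(grepl("^AGG[TC]$", seqs)))
  })
  do.call(rbind, rows)
}
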