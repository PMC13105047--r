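# GC metagene profiles, windowed GC, tetramer enrichment, splice-site IC ----

gc_fraction <- function(seqs) {
  ss <- Biostrings::DNAStringSet(seqs)
  as.numeric(Biostrings::letterFrequency(ss, "GC", as.prob = TRUE))
}

# per-bin GC of one sequence, length-normalized to `bins` slices; sequences
# shorter than `bins` are interpolated from per-base values
binned_gc <- function(seq, bins) {
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gc <- as.numeric(ch %in% c("G", "C"))
  if (L >= bins) {
    bin <- floor((seq_len(L) - 1L) * bins / L) + 1L
    as.numeric(tapply(gc, bin, mean))
  } else if (L >= 2L) {
    stats::approx(seq(0, 1, length.out = L), gc,
                  xout = seq(0, 1, length.out = bins))$y
  } else {
    rep(gc[1L], bins)
  }
}

#' Metagene GC-content profile of introns and flanking exons
#'
#' For each classified intron, the upstream exon, the intron and the
#' downstream exon (all in transcription orientation) are length-normalized
#' into `bins` equal slices and per-slice GC fractions are averaged within
#' each RS class.
#'
#' @param classified result of [classify_junctions()] (its `introns` table;
#'   a data.frame with `rs_class` also works).
#' @param annotation the [genome_annotation()] providing flanking exons.
#' @param genome DNAStringSet.
#' @param bins slices per segment (default 50).
#' @return data.frame `rs_class`, `segment`, `bin`, `mean_gc`, `n`.
#' @export
metagene_gc <- function(classified, annotation, genome, bins = 50L) {
  ci <- data.table::as.data.table(if (is.data.frame(classified)) classified
                                  else classified$introns)
  if (nrow(ci) == 0L) stop("no classified introns")
  fl <- flanking_exons(ci, annotation)
  ci <- fl$introns
  rows <- list()
  for (seg in c("upstream_exon", "intron", "downstream_exon")) {
    co <- switch(seg, upstream_exon = fl$upstream, intron = ci[, .(start, end)],
                 downstream_exon = fl$downstream)
    ok <- !is.na(co$start) & (co$end >= co$start)
    if (!any(ok)) next
    seqs <- as.character(Biostrings::DNAStringSet(genome[ci$chrom[ok]],
                                                  start = co$start[ok], end = co$end[ok]))
    neg <- ci$strand[ok] == "-"
    if (any(neg)) {
      seqs[neg] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[neg])))
    }
    prof <- vapply(seqs, binned_gc, numeric(bins), bins = bins)
    cls <- ci$rs_class[ok]
    for (cl in unique(cls)) {
      sub <- prof[, cls == cl, drop = FALSE]
      rows[[paste(seg, cl)]] <- data.frame(
        rs_class = cl, segment = seg, bin = seq_len(bins),
        mean_gc = rowMeans(sub), n = ncol(sub), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic intervals of the exons flanking each intron (transcription sense)
flanking_exons <- function(ci, annotation) {
  ex <- data.table::as.data.table(annotation$exons)
  data.table::setorder(ex, transcript_id, start)
  up <- data.table::data.table(start = rep(NA_integer_, nrow(ci)),
                               end = rep(NA_integer_, nrow(ci)))
  dn <- data.table::copy(up)
  exs <- split(ex, by = "transcript_id")
  for (i in seq_len(nrow(ci))) {
    e <- exs[[ci$transcript_id[i]]]
    if (is.null(e)) next
    left <- e[end == ci$start[i] - 1L]
    right <- e[start == ci$end[i] + 1L]
    if (nrow(left) == 1L && nrow(right) == 1L) {
      if (ci$strand[i] == "+") {
        up[i, `:=`(start = left$start, end = left$end)]
        dn[i, `:=`(start = right$start, end = right$end)]
      } else {
        up[i, `:=`(start = right$start, end = right$end)]
        dn[i, `:=`(start = left$start, end = left$end)]
      }
    }
  }
  list(introns = ci, upstream = up, downstream = dn)
}

#' Per-sequence GC fraction in fixed splice-site windows
#'
#' @param site_sequences data.frame from [extract_site_sequences()] (the
#'   conventional windows are -50..+100 for 5' sites and -100..+50 for 3'
#'   sites).
#' @return the input with a `gc` column, plus a per-class summary in
#'   attribute `summary`.
#' @export
window_gc <- function(site_sequences) {
  out <- site_sequences
  out$gc <- gc_fraction(out$sequence)
  dt <- data.table::as.data.table(out)
  sm <- dt[, .(n = .N, mean_gc = mean(gc), median_gc = stats::median(gc)),
           by = .(site_type, rs_class)]
  attr(out, "summary") <- data.table::setDF(sm)
  out
}

#' Tetramer enrichment between two sequence groups
#'
#' Counts overlapping k-mer occurrences per group; per k-mer the effect is
#' `log2fc = log2((count_a + 0.5)/total_a) - log2((count_b + 0.5)/total_b)`
#' (Haldane pseudo-count) and the p-value a two-sided Fisher's exact test on
#' the (k-mer vs all-other) x (group) 2x2 table, BH-corrected.
#'
#' @param group_a_seqs,group_b_seqs character vectors of sequences.
#' @param k k-mer length (default 4).
#' @return data.frame `kmer`, `count_a`, `count_b`, `log2fc`, `p_value`,
#'   `q_value`.
#' @export
tetramer_enrichment <- function(group_a_seqs, group_b_seqs, k = 4L) {
  if (length(group_a_seqs) == 0L || length(group_b_seqs) == 0L) {
    stop("both sequence groups must be non-empty")
  }
  ca <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(group_a_seqs), width = k))
  cb <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(group_b_seqs), width = k))
  ta <- sum(ca); tb <- sum(cb)
  log2fc <- log2((ca + 0.5) / ta) - log2((cb + 0.5) / tb)
  p <- vapply(seq_along(ca), function(i) {
    stats::fisher.test(matrix(c(ca[i], ta - ca[i], cb[i], tb - cb[i]), 2L))$p.value
  }, 0)
  q <- stats::p.adjust(p, method = "BH")
  data.frame(kmer = names(ca), count_a = as.integer(ca), count_b = as.integer(cb),
             log2fc = unname(log2fc), p_value = p, q_value = q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-position information content of aligned sequences
#'
#' `IC = 2 + sum_b f_b log2 f_b` bits against a uniform background with a
#' 1e-6 pseudo-count; 2 bits for an invariant column, 0 for a uniform one.
#'
#' @param site_sequences data.frame from [extract_site_sequences()] or a
#'   character vector of equal-length sequences.
#' @return data.frame `position` (window offsets when known), `ic`.
#' @export
pwm_information <- function(site_sequences) {
  seqs <- if (is.data.frame(site_sequences)) site_sequences$sequence else site_sequences
  if (length(seqs) == 0L) stop("no sequences")
  W <- unique(nchar(seqs))
  if (length(W) != 1L) stop("sequences must be aligned to equal length")
  cm <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs))
  cm <- cm[intersect(c("A", "C", "G", "T"), rownames(cm)), , drop = FALSE]
  f <- sweep(cm + 1e-6, 2L, colSums(cm + 1e-6), "/")
  ic <- 2 + colSums(f * log2(f))
  win <- if (is.data.frame(site_sequences)) attr(site_sequences, "window") else NULL
  pos <- if (!is.null(win)) win[1L] + seq_len(W) - 1L else seq_len(W) - 1L
  data.frame(position = pos, ic = pmin(2, pmax(0, ic)))
}
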