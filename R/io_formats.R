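#' @import data.table
#' @importFrom stats rbinom rnbinom rnorm runif rbeta rgamma setNames
#'   fisher.test wilcox.test p.adjust ecdf median sd quantile aggregate uniroot
#' @importFrom utils head tail
NULL

# Internal convention everywhere: 1-based inclusive genomic intervals (the
# STAR SJ dialect). BED inputs are converted at this boundary and never after.

#' Build a genome annotation from an exon table
#'
#' Groups exons per transcript, validates them, and derives introns as the
#' gaps between consecutive exons (1-based inclusive). Intron order and
#' `position_class` (`first`/`middle`/`last`) follow transcription order, so
#' on the minus strand the first intron is the highest-coordinate one.
#'
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `strand` (one row per exon, 1-based inclusive).
#' @return An object of class `genome_annotation`: a list with `genes`,
#'   `exons` (exon_rank in transcription order) and `introns` (with
#'   `intron_rank` and `position_class`).
#' @export
genome_annotation <- function(exons) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0L) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  ex <- data.table::as.data.table(exons)[, req, with = FALSE]
  if (any(ex$start > ex$end)) stop("exon with start > end")
  if (!all(ex$strand %in% c("+", "-"))) stop("exon strand must be '+' or '-'")
  data.table::setorder(ex, transcript_id, start)
  # non-overlap within transcript
  bad <- ex[, .(ok = all(diff(start) > 0) && all(start[-1] > end[-.N]) || .N == 1L),
            by = transcript_id][ok == FALSE]
  if (nrow(bad) > 0L) {
    stop("overlapping or unsorted exons in transcript(s): ",
         paste(utils::head(bad$transcript_id, 3), collapse = ", "))
  }
  ex[, genomic_rank := seq_len(.N), by = transcript_id]
  ex[, exon_rank := ifelse(strand == "+", genomic_rank, .N - genomic_rank + 1L),
     by = transcript_id]

  introns <- ex[, {
    if (.N >= 2L) {
      list(chrom = chrom[1L], gene_id = gene_id[1L], strand = strand[1L],
           start = end[-.N] + 1L, end = start[-1L] - 1L)
    } else {
      list(chrom = character(0), gene_id = character(0), strand = character(0),
           start = integer(0), end = integer(0))
    }
  }, by = transcript_id]
  if (nrow(introns) > 0L) {
    if (any(introns$start > introns$end)) stop("zero-length intron (adjacent exons)")
    introns[, genomic_rank := seq_len(.N), by = transcript_id]
    introns[, intron_rank := ifelse(strand == "+", genomic_rank, .N - genomic_rank + 1L),
            by = transcript_id]
    introns[, n_introns := .N, by = transcript_id]
    introns[, position_class := ifelse(intron_rank == 1L, "first",
                                ifelse(intron_rank == n_introns, "last", "middle"))]
    # a single intron is 5'-most, so classed "first"
    introns[n_introns == 1L, position_class := "first"]
    introns[, length := end - start + 1L]
    introns[, genomic_rank := NULL]
  } else {
    introns <- data.table::data.table(
      transcript_id = character(0), chrom = character(0), gene_id = character(0),
      strand = character(0), start = integer(0), end = integer(0),
      intron_rank = integer(0), n_introns = integer(0),
      position_class = character(0), length = integer(0))
  }
  genes <- unique(ex[, .(gene_id, chrom, strand)])
  ex[, genomic_rank := NULL]
  structure(list(genes = data.table::setDF(genes),
                 exons = data.table::setDF(ex),
                 introns = data.table::setDF(introns)),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts, %d exons, %d introns\n",
              nrow(x$genes), length(unique(x$exons$transcript_id)),
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Read a GTF annotation
#'
#' Reads exon features from a GTF file (via rtracklayer) and derives the
#' per-transcript intron structure.
#'
#' @param path GTF file with `gene_id` and `transcript_id` attributes on exon
#'   rows.
#' @return A [genome_annotation()] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("GTF parse error in ", path, ": ",
                                          conditionMessage(e)))
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) stop("no exon features in ", path)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon rows must carry gene_id and transcript_id attributes: ", path)
  }
  genome_annotation(data.frame(
    gene_id = gr$gene_id, transcript_id = gr$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' Read a STAR-dialect splice-junction table
#'
#' Nine tab-separated columns: chrom, start, end, strand code (0 unknown /
#' 1 `+` / 2 `-`), motif code, annotated code, unique reads, multimapped
#' reads, max overhang. Coordinates are kept 1-based inclusive (first and
#' last intronic base). No read filtering happens here.
#'
#' @param path file path.
#' @param phase `"nascent"` or `"mature"`.
#' @param sample_id sample label attached to every junction.
#' @return data.frame of junctions with decoded strand.
#' @export
read_sj_table <- function(path, phase = c("nascent", "mature"), sample_id = basename(path)) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("SJ table not found: ", path)
  if (file.size(path) == 0L) {
    return(empty_junctions(phase, sample_id))
  }
  sj <- data.table::fread(path, header = FALSE, sep = "\t", colClasses = "character")
  if (ncol(sj) != 9L) stop("SJ table must have 9 columns, got ", ncol(sj), ": ", path)
  data.table::setnames(sj, c("chrom", "start", "end", "strand_code", "motif",
                             "annotated", "unique_reads", "multimap_reads", "overhang"))
  intcols <- c("start", "end", "strand_code", "motif", "annotated",
               "unique_reads", "multimap_reads", "overhang")
  for (cc in intcols) {
    v <- sj[[cc]]
    if (any(!grepl("^-?[0-9]+$", v))) {
      stop("non-integer value in SJ column '", cc, "' of ", path)
    }
    data.table::set(sj, j = cc, value = as.integer(v))
  }
  if (any(sj$start > sj$end)) stop("SJ junction with start > end in ", path)
  if (any(sj$unique_reads < 0L)) stop("negative unique read count in ", path)
  sj[, strand := c("*", "+", "-")[strand_code + 1L]]
  sj[, annotated := annotated != 0L]
  out <- sj[, .(chrom, start, end, strand, unique_reads, multimap_reads, annotated)]
  out[, phase := phase]
  out[, sample_id := sample_id]
  data.table::setDF(out)
}

empty_junctions <- function(phase = character(0), sample_id = character(0)) {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0), unique_reads = integer(0),
             multimap_reads = integer(0), annotated = logical(0),
             phase = rep(phase, 0), sample_id = rep(sample_id, 0),
             stringsAsFactors = FALSE)
}

#' Write junctions back to the 9-column SJ dialect
#'
#' @param junctions data.frame as returned by [read_sj_table()] (an
#'   `overhang`/`motif` column is optional and defaults to 0).
#' @param path output file.
#' @export
write_sj_table <- function(junctions, path) {
  j <- data.table::as.data.table(junctions)
  strand_code <- match(j$strand, c("*", "+", "-")) - 1L
  if (anyNA(strand_code)) stop("strand must be one of '*', '+', '-'")
  out <- data.table::data.table(
    chrom = j$chrom, start = j$start, end = j$end, strand = strand_code,
    motif = if ("motif" %in% names(j)) j$motif else 0L,
    annotated = as.integer(if ("annotated" %in% names(j)) j$annotated else 0L),
    unique_reads = j$unique_reads,
    multimap_reads = if ("multimap_reads" %in% names(j)) j$multimap_reads else 0L,
    overhang = if ("overhang" %in% names(j)) j$overhang else 0L)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a bedMethyl (BED9+2) WGBS track
#'
#' ENCODE-style bedMethyl: BED9 plus column 10 = read coverage and column
#' 11 = percent methylated. BED's 0-based half-open starts are converted to
#' 1-based positions here and nowhere else. Records with a percent outside
#' \[0, 100\] are rejected; their count is attached as attribute
#' `n_rejected` and reported in a warning.
#'
#' @param path bedMethyl file.
#' @return data.frame with `chrom`, `position` (1-based C of the CpG),
#'   `strand`, `coverage`, `percent_methylated`.
#' @export
read_bedmethyl <- function(path) {
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)
  empty <- data.frame(chrom = character(0), position = integer(0),
                      strand = character(0), coverage = integer(0),
                      percent_methylated = numeric(0), stringsAsFactors = FALSE)
  if (file.size(path) == 0L) return(empty)
  bm <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(bm) < 11L) stop("bedMethyl needs >= 11 columns (BED9 + coverage + percent): ", path)
  out <- data.table::data.table(
    chrom = as.character(bm[[1L]]),
    position = as.integer(bm[[2L]]) + 1L,   # 0-based half-open -> 1-based
    strand = as.character(bm[[6L]]),
    coverage = as.integer(bm[[10L]]),
    percent_methylated = as.numeric(bm[[11L]]))
  bad <- out$percent_methylated < 0 | out$percent_methylated > 100 | is.na(out$percent_methylated)
  if (any(bad)) {
    warning(sum(bad), " bedMethyl record(s) with percent outside [0,100] rejected")
    out <- out[!bad]
  }
  if (any(out$coverage < 0L)) stop("negative coverage in ", path)
  res <- data.table::setDF(out)
  attr(res, "n_rejected") <- sum(bad)
  res
}

#' Write methylation records as bedMethyl
#' @param records data.frame as from [read_bedmethyl()].
#' @param path output file.
#' @export
write_bedmethyl <- function(records, path) {
  r <- data.table::as.data.table(records)
  out <- data.table::data.table(
    chrom = r$chrom, start = r$position - 1L, end = r$position,
    name = "CpG", score = pmin(1000L, as.integer(r$coverage)),
    strand = if ("strand" %in% names(r)) r$strand else "+",
    thickStart = r$position - 1L, thickEnd = r$position, rgb = "0,0,0",
    coverage = r$coverage, percent = r$percent_methylated)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a TPM expression table
#'
#' TSV with header columns `transcript_id`, `gene_id`, `TPM`. Gene-level
#' expression is obtained by summing transcript TPM per gene.
#'
#' @param path TSV file.
#' @return data.frame with the three columns.
#' @export
read_tpm <- function(path) {
  if (!file.exists(path)) stop("TPM table not found: ", path)
  tp <- data.table::fread(path, header = TRUE, sep = "\t")
  req <- c("transcript_id", "gene_id", "TPM")
  if (!all(req %in% names(tp))) {
    stop("TPM table must have columns transcript_id, gene_id, TPM: ", path)
  }
  data.table::setDF(tp[, req, with = FALSE])
}

#' Gene-level TPM (transcript TPM summed per gene)
#' @param tpm data.frame from [read_tpm()].
#' @return data.frame `gene_id`, `TPM`.
#' @export
gene_tpm <- function(tpm) {
  dt <- data.table::as.data.table(tpm)
  data.table::setDF(dt[, .(TPM = sum(TPM)), by = gene_id])
}

#' Read a genome FASTA
#' @param path FASTA file; names are truncated at the first whitespace.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Extract a strand-aware sequence window around a genomic anchor
#'
#' `window = c(lo, hi)` is interpreted in transcription orientation with
#' position 0 at `pos`; minus-strand windows are reverse-complemented so the
#' returned sequence always reads 5' to 3'. Windows that would run off the
#' contig return `NA`.
#'
#' @param genome DNAStringSet.
#' @param chrom,pos,strand anchor (1-based genomic coordinate).
#' @param window integer length-2 vector `c(lo, hi)`, inclusive offsets.
#' @return character vector of sequences (NA where truncated by an edge).
#' @export
extract_window <- function(genome, chrom, pos, strand, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  n <- length(pos)
  chrom <- rep_len(chrom, n); strand <- rep_len(strand, n)
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss) > 0L) stop("contig(s) missing from genome: ", paste(miss, collapse = ", "))
  gs <- ifelse(strand == "+", pos + window[1], pos - window[2])
  ge <- ifelse(strand == "+", pos + window[2], pos - window[1])
  clen <- Biostrings::width(genome)[match(chrom, names(genome))]
  ok <- gs >= 1L & ge <= clen & strand %in% c("+", "-")
  out <- rep(NA_character_, n)
  if (any(ok)) {
    seqs <- character(sum(ok))
    idx <- which(ok)
    sub <- Biostrings::DNAStringSet(genome[chrom[idx]], start = gs[idx], end = ge[idx])
    neg <- strand[idx] == "-"
    if (any(neg)) sub[neg] <- Biostrings::reverseComplement(sub[neg])
    out[idx] <- as.character(sub)
  }
  out
}

# shared junction identity used for phase comparisons and deduplication
junction_key <- function(j) paste(j$chrom, j$start, j$end, j$strand, sep = ":")
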