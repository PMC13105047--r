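# Mapping in-vitro RBNS k-mer preferences onto splice-site positions ---------

#' Load RBNS k-mer enrichment tables into a protein x k-mer matrix
#'
#' For each protein the concentration whose maximum k-mer R value is largest
#' is selected; the matrix is assembled over the common k-mer vocabulary.
#'
#' @param tables a data.frame (or list of data.frames) with columns
#'   `protein`, `concentration`, `kmer`, `R`.
#' @return object of class `rbns_matrix`: list with `R` (proteins x k-mers),
#'   `k`, `concentrations` (named per protein).
#' @export
load_rbns <- function(tables) {
  dt <- if (is.data.frame(tables)) data.table::as.data.table(tables)
        else data.table::rbindlist(tables, use.names = TRUE)
  req <- c("protein", "concentration", "kmer", "R")
  if (!all(req %in% names(dt))) stop("RBNS table needs columns: ", paste(req, collapse = ", "))
  klen <- unique(nchar(dt$kmer))
  if (length(klen) != 1L) stop("mixed k-mer lengths within an RBNS run: ",
                               paste(klen, collapse = ", "))
  if (any(dt$R <= 0)) stop("RBNS R values must be positive")
  best <- dt[, .(max_R = max(R)), by = .(protein, concentration)]
  best <- best[order(-max_R), .SD[1L], by = protein]
  sel <- merge(dt, best[, .(protein, concentration)], by = c("protein", "concentration"))
  vocab <- all_kmers(klen)
  prot <- sort(unique(sel$protein))
  R <- matrix(NA_real_, length(prot), length(vocab), dimnames = list(prot, vocab))
  idx <- cbind(match(sel$protein, prot), match(sel$kmer, vocab))
  if (anyNA(idx[, 2L])) stop("non-ACGT k-mer in RBNS table")
  R[idx] <- sel$R
  if (anyNA(R)) {
    bad <- prot[which(rowSums(is.na(R)) > 0L)[1L]]
    stop("k-mer(s) missing for protein ", bad)
  }
  conc <- stats::setNames(best$concentration[match(prot, best$protein)], prot)
  structure(list(R = R, k = klen, concentrations = conc), class = "rbns_matrix")
}

# bins x 4^k k-mer start fraction matrix over [-span, span) in `bin`-nt units
bin_fraction_matrix <- function(seqs, window, k, bin, span) {
  if (window[1L] > -span || window[2L] < span - 1L) {
    stop("sequences must cover -span..+span-1 (window ",
         window[1L], "..", window[2L], " given)")
  }
  vocab <- all_kmers(k)
  ids <- kmer_id_matrix(seqs, k)          # n_seq x n_start
  offsets <- window[1L] + seq_len(ncol(ids)) - 1L
  n_bins <- 2L * span %/% bin
  bin_of <- (offsets + span) %/% bin + 1L
  keep <- offsets >= -span & offsets <= span - 1L & bin_of >= 1L & bin_of <= n_bins
  f <- matrix(0, n_bins, length(vocab), dimnames = list(NULL, vocab))
  for (b in seq_len(n_bins)) {
    cols <- which(keep & bin_of == b)
    if (length(cols) == 0L) next
    counts <- tabulate(ids[, cols], nbins = length(vocab))
    if (sum(counts) > 0) f[b, ] <- counts / sum(counts)
  }
  rownames(f) <- paste0("bin", seq_len(n_bins))
  attr(f, "bin_start") <- -span + (seq_len(n_bins) - 1L) * bin
  f
}

#' Position-resolved RBNS protein enrichment around splice sites
#'
#' Per (site_type, RS group) and per positional bin (default 15-nt units over
#' -75..+75), the k-mer start fraction vector `f` is multiplied with the
#' protein k-mer matrix: `E[bin, protein] = sum_k f_k R[protein, k]`.
#' Log2 fold changes are computed for the paired contrasts: canonical sites
#' compare RS introns against non-RS introns, and recursive sites compare the
#' recursive site against the canonical site of the same type within RS
#' introns.
#'
#' @param site_sequences data.frame from [extract_site_sequences()] (one or
#'   several site types concatenated; windows must cover `-span..span-1`).
#' @param rbns an [load_rbns()] matrix.
#' @param bin bin width in nt (default 15).
#' @param span half-window in nt (default 75).
#' @return object of class `rbns_position_enrichment`: list with `E` (long
#'   data.frame: site_type, rs_group, bin, bin_start, protein, E), `log2fc`
#'   (comparison, bin, bin_start, protein, log2fc) and `f` (the per-group
#'   fraction matrices).
#' @export
position_enrichment <- function(site_sequences, rbns, bin = 15L, span = 75L) {
  stopifnot(inherits(rbns, "rbns_matrix"))
  ss <- data.table::as.data.table(site_sequences)
  win <- attr(site_sequences, "window")
  if (is.null(win)) stop("site_sequences must carry their window attribute")
  ss[, rs_group := ifelse(rs_class %in% c("RS5", "RS3", "nested"), "RS", "noRS")]
  keygrp <- unique(ss[, .(site_type, rs_group)])
  fmats <- list(); Erows <- list()
  for (i in seq_len(nrow(keygrp))) {
    st <- keygrp$site_type[i]; gr <- keygrp$rs_group[i]
    seqs <- ss[site_type == st & rs_group == gr]$sequence
    f <- bin_fraction_matrix(seqs, win, rbns$k, bin, span)
    E <- f %*% t(rbns$R)
    key <- paste(st, gr, sep = "|")
    fmats[[key]] <- f
    Erows[[key]] <- data.frame(
      site_type = st, rs_group = gr,
      bin = rep(seq_len(nrow(E)), ncol(E)),
      bin_start = rep(attr(f, "bin_start"), ncol(E)),
      protein = rep(colnames(E), each = nrow(E)),
      E = as.vector(E), stringsAsFactors = FALSE)
  }
  l2 <- function(a, b, label) {
    Ea <- stats::setNames(Erows[[a]]$E, NULL); Eb <- Erows[[b]]$E
    data.frame(comparison = label, bin = Erows[[a]]$bin,
               bin_start = Erows[[a]]$bin_start, protein = Erows[[a]]$protein,
               log2fc = log2(pmax(Ea, 1e-9)) - log2(pmax(Eb, 1e-9)),
               stringsAsFactors = FALSE)
  }
  fc <- list()
  for (st in c("canonical5", "canonical3")) {
    a <- paste(st, "RS", sep = "|"); b <- paste(st, "noRS", sep = "|")
    if (!is.null(Erows[[a]]) && !is.null(Erows[[b]])) {
      fc[[st]] <- l2(a, b, paste0(st, ":RS_vs_noRS"))
    }
  }
  for (rs in c("5", "3")) {
    a <- paste0("recursive", rs, "|RS"); b <- paste0("canonical", rs, "|RS")
    if (!is.null(Erows[[a]]) && !is.null(Erows[[b]])) {
      fc[[a]] <- l2(a, b, paste0("recursive", rs, ":recursive_vs_canonical"))
    }
  }
  structure(list(E = do.call(rbind, c(Erows, list(make.row.names = FALSE))),
                 log2fc = if (length(fc) > 0L) do.call(rbind, c(fc, list(make.row.names = FALSE))) else NULL,
                 f = fmats, bin = bin, span = span),
            class = "rbns_position_enrichment")
}

#' Rank proteins by their strongest positional log2 fold change
#'
#' Per protein the maximum absolute log2 fold change over all bins and
#' contrasts, ranked descending (ties broken by protein name).
#'
#' @param enrichment an [position_enrichment()] result.
#' @param top_n rows to keep (default 30).
#' @return data.frame `protein`, `max_abs_log2fc`, `best_comparison`,
#'   `best_bin_start`, `rank`.
#' @export
rank_proteins <- function(enrichment, top_n = 30L) {
  stopifnot(inherits(enrichment, "rbns_position_enrichment"))
  fc <- data.table::as.data.table(enrichment$log2fc)
  if (is.null(fc) || nrow(fc) == 0L) stop("no log2fc contrasts available")
  best <- fc[order(-abs(log2fc), protein),
             .(max_abs_log2fc = abs(log2fc)[1L], best_comparison = comparison[1L],
               best_bin_start = bin_start[1L]), by = protein]
  best <- best[order(-max_abs_log2fc, protein)]
  best[, rank := .I]
  data.table::setDF(utils::head(best, top_n))
}
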