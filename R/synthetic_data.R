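# Synthetic study generator -------------------------------------------------
#
# Emulates the inputs the recursive-splicing analysis consumes: a genome with
# single-isoform multi-exon genes, long first introns, planted CG-rich motifs
# flanking first-intron 5'SS of RS genes, purine-diluted pyrimidine tracts at
# their 3'SS, internal AGGU recursive sites, nascent-only recursive junctions
# with negative-binomial read support, first-exon CpG methylation levels, TPM,
# and an in-vitro RBNS-style k-mer enrichment table with planted binders.

#' Configuration for the synthetic recursive-splicing bundle
#'
#' Defaults are the study conditions used throughout the test-suite: marginal
#' first-intron and downstream RS rates of 0.4 coupled at an odds ratio of
#' 2.2, two recursive sites per RS intron, 40% of planted ratchet points
#' degraded away from the AGGU consensus, negative-binomial junction support
#' (mean 8, dispersion 0.5) truncated at one read, and Beta(2,8) vs Beta(6,4)
#' first-exon methylation for RS vs non-RS genes.
#'
#' @param n_genes number of (single-isoform) genes.
#' @param introns_per_gene integer range `c(lo, hi)` of introns per gene.
#' @param first_intron_log10,downstream_intron_log10 `c(mean, sd)` of the
#'   log10 intron-length distributions (nt).
#' @param rs_intron_log10_shift added to the log10 length mean of introns that
#'   carry recursive sites (RS favours long introns).
#' @param exon_length_range uniform exon length range (nt).
#' @param background_base_probs named A/C/G/T sampling probabilities.
#' @param rs_gene_fraction marginal probability of RS, used for both the
#'   first-intron and the downstream indicator; 0 yields an all-basic bundle.
#' @param coupling_odds_ratio target odds ratio between first-intron RS and
#'   downstream RS (the conditional downstream probabilities are solved from
#'   it and the marginals).
#' @param rs_class_probs probabilities of RS5/RS3/nested for an RS intron.
#' @param n_recursive_sites recursive junctions planted per RS intron.
#' @param aggu_degraded_fraction fraction of recursive sites whose AGGU
#'   ratchet tetramer is left as background sequence.
#' @param cg_motif_strength excess CG-dinucleotide start density planted in
#'   `cg_window` around the first-intron 5'SS of RS genes.
#' @param cg_window,ppt_window windows (transcription orientation, position 0
#'   = first/last intron base) for the CG motif and the pyrimidine tract.
#' @param ppt_base_probs,ppt_purine_dilution polypyrimidine-tract composition
#'   of non-RS first introns, and the mixing weight toward a U/A-shifted
#'   tract for RS first introns.
#' @param methylation_beta_rs,methylation_beta_down,methylation_beta_basic
#'   Beta parameters of first-exon methylation for first-intron-RS genes,
#'   downstream-RS-only genes, and RS-free genes.
#' @param read_count_mean,read_count_dispersion negative-binomial junction
#'   read support (size = 1/dispersion), truncated at >= 1.
#' @param tpm_log10 `c(mean, sd)` of log10 gene TPM.
#' @param tpm_rs_log10_shift log10 TPM shift for RS genes.
#' @param rbns_k k-mer length of the synthetic RBNS table.
#' @param n_nascent_samples number of nascent SJ tables (DRB-washout time
#'   points); mature RNA is a single sample.
#' @param noise_junction_fraction fraction of extra intergenic junctions
#'   (overlapping no intron) added to nascent tables.
#' @param genes_per_chrom,intergenic_gap genome layout.
#' @param seed mandatory RNG seed; same seed, same bundle, byte for byte.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 200L,
                             introns_per_gene = c(3L, 6L),
                             first_intron_log10 = c(3.0, 0.15),
                             downstream_intron_log10 = c(2.55, 0.15),
                             rs_intron_log10_shift = 0.25,
                             exon_length_range = c(150L, 300L),
                             background_base_probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             rs_gene_fraction = 0.4,
                             coupling_odds_ratio = 2.2,
                             rs_class_probs = c(RS5 = 0.6, RS3 = 0.25, nested = 0.15),
                             n_recursive_sites = 2L,
                             aggu_degraded_fraction = 0.4,
                             cg_motif_strength = 0.3,
                             cg_window = c(-30L, 50L),
                             ppt_window = c(-50L, -5L),
                             ppt_base_probs = c(A = 0.08, C = 0.42, G = 0.08, T = 0.42),
                             ppt_purine_dilution = 0.5,
                             methylation_beta_rs = c(2, 8),
                             methylation_beta_down = c(4, 6),
                             methylation_beta_basic = c(6, 4),
                             read_count_mean = 8,
                             read_count_dispersion = 0.5,
                             tpm_log10 = c(1.0, 0.4),
                             tpm_rs_log10_shift = 0.3,
                             rbns_k = 5L,
                             n_nascent_samples = 2L,
                             noise_junction_fraction = 0.02,
                             genes_per_chrom = 100L,
                             intergenic_gap = 400L,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$rs_gene_fraction, cfg$aggu_degraded_fraction,
             cfg$noise_junction_fraction, cfg$background_base_probs,
             cfg$rs_class_probs, cfg$ppt_base_probs, cfg$ppt_purine_dilution)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$coupling_odds_ratio <= 0) stop("coupling_odds_ratio must be > 0")
  if (is.null(cfg$seed) || is.na(cfg$seed)) stop("seed is mandatory")
  if (abs(sum(cfg$background_base_probs) - 1) > 1e-8) stop("background_base_probs must sum to 1")
  if (cfg$n_recursive_sites < 1L) stop("n_recursive_sites must be >= 1")
  if (cfg$introns_per_gene[1] < 1L) stop("introns_per_gene must be >= 1")
  if (cfg$cg_motif_strength > 0.45) stop("cg_motif_strength too large to plant non-overlapping CG dinucleotides")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Solve the conditional downstream-RS probabilities for a target odds ratio
#'
#' Given the marginal first-intron RS probability `p1`, the marginal
#' downstream-RS probability `p2` and a target odds ratio, returns `q1 =
#' P(downstream RS | first RS)` and `q0 = P(downstream RS | first basic)`
#' such that odds(q1)/odds(q0) equals the target and the marginal is `p2`.
#'
#' @keywords internal
solve_coupling <- function(p1, p2, odds_ratio) {
  if (p2 <= 0) return(c(q1 = 0, q0 = 0))
  if (p2 >= 1) return(c(q1 = 1, q0 = 1))
  if (p1 <= 0 || p1 >= 1 || odds_ratio == 1) return(c(q1 = p2, q0 = p2))
  q1_of <- function(q0) {
    o <- odds_ratio * q0 / (1 - q0)
    o / (1 + o)
  }
  f <- function(q0) p1 * q1_of(q0) + (1 - p1) * q0 - p2
  q0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(q1 = q1_of(q0), q0 = q0)
}

# zero-truncated negative binomial draws (size = 1/dispersion)
rnb_pos <- function(n, mu, dispersion) {
  if (n == 0L) return(integer(0))
  x <- stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  while (any(x == 0L)) {
    z <- x == 0L
    x[z] <- stats::rnbinom(sum(z), mu = mu, size = 1 / dispersion)
  }
  x
}

# core CG planter on a character vector (window of bases); uses ambient RNG.
# Raises the expected CG-dinucleotide start density by `shift`, correcting
# for the background starts destroyed by overwriting (a planted CG removes
# ~3 background dinucleotide slots of density b each).
plant_cg_chars <- function(chars, shift) {
  lw <- length(chars)
  if (lw < 2L || shift <= 0) return(chars)
  slots <- lw - 1L
  b <- sum(chars[-lw] == "C" & chars[-1L] == "G") / slots
  m <- round(shift * slots / max(1e-9, 1 - 3 * b))
  m <- min(m, floor(lw / 2L))
  if (m < 1L) return(chars)
  cand <- sample.int(slots)          # candidate start positions, random order
  picked <- integer(0)
  for (p in cand) {
    if (length(picked) >= m) break
    if (all(abs(picked - p) >= 2L)) picked <- c(picked, p)
  }
  chars[picked] <- "C"
  chars[picked + 1L] <- "G"
  chars
}

#' Plant a CG-dinucleotide composition shift in a sequence window
#'
#' Only the window changes; the expected CG-dinucleotide start frequency in
#' the window is raised by `composition_shift` over its background. A shift
#' of 0 (or an empty window) returns the input unchanged.
#'
#' @param sequence a single DNA string.
#' @param window 1-based inclusive `c(start, end)` within the sequence; a
#'   window with `end < start` has length 0.
#' @param composition_shift excess CG-dinucleotide start density to plant.
#' @param seed optional seed; when given the call is reproducible and leaves
#'   the ambient RNG untouched.
#' @return the modified sequence string.
#' @export
plant_motif <- function(sequence, window, composition_shift, seed = NULL) {
  stopifnot(length(sequence) == 1L, length(window) == 2L)
  n <- nchar(sequence)
  if (window[2] < window[1]) return(sequence)
  if (window[1] < 1L || window[2] > n) stop("window out of range for sequence of length ", n)
  if (composition_shift == 0) return(sequence)
  if (composition_shift < 0 || composition_shift > 1) stop("composition_shift must be in [0, 1]")
  run <- function() {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    idx <- window[1]:window[2]
    chars[idx] <- plant_cg_chars(chars[idx], composition_shift)
    paste(chars, collapse = "")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  run()
}

revcomp_chars <- function(chars) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[chars])
}

#' Generate the full synthetic input bundle
#'
#' Produces a mutually consistent FASTA + GTF pair, nascent and mature
#' splice-junction tables, a TPM table, a bedMethyl methylation track, an
#' RBNS k-mer enrichment table, and truth tables recording the planted RS
#' status, recursive-site coordinates and motif flags of every intron.
#' Recursive junctions appear only in nascent tables and only for RS introns;
#' every planted recursive site lies at least 75 nt from both annotated
#' splice sites of a host intron at least 150 nt long.
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given, all bundle files are written
#'   there and their paths returned in `$paths`.
#' @return a list with `annotation`, `genome`, `nascent` (list of junction
#'   tables), `mature`, `tpm`, `methylation`, `rbns`, `truth` (lists
#'   `introns`, `sites`, `transcripts`) and `config`.
#' @export
generate_rs_bundle <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  transcript_id <- paste0(gene_id, ".t1")
  strand <- sample(c("+", "-"), n, replace = TRUE)
  m <- sample(seq.int(cfg$introns_per_gene[1], cfg$introns_per_gene[2]), n, replace = TRUE)

  # transcript-level RS coupling (2x2 model hitting the target OR in expectation)
  p <- cfg$rs_gene_fraction
  q <- solve_coupling(p, p, cfg$coupling_odds_ratio)
  first_rs <- stats::runif(n) < p
  down_any <- stats::runif(n) < ifelse(first_rs, q["q1"], q["q0"])
  down_any[m < 2L] <- FALSE

  # per-intron tables -------------------------------------------------------
  gi <- rep.int(seq_len(n), m)
  rank <- unlist(lapply(m, seq_len), use.names = FALSE)
  is_first <- rank == 1L
  is_rs <- logical(length(gi))
  is_rs[is_first] <- first_rs[gi[is_first]]
  # downstream RS introns: each downstream intron w.p. 0.5 given the
  # transcript indicator, forcing at least one
  dn <- !is_first & down_any[gi]
  is_rs[dn] <- stats::runif(sum(dn)) < 0.5
  for (g in which(down_any & m >= 2L)) {
    sel <- which(gi == g & !is_first)
    if (!any(is_rs[sel])) is_rs[sample(sel, 1L)] <- TRUE
  }

  ln_mean <- ifelse(is_first, cfg$first_intron_log10[1], cfg$downstream_intron_log10[1]) +
    ifelse(is_rs, cfg$rs_intron_log10_shift, 0)
  ln_sd <- ifelse(is_first, cfg$first_intron_log10[2], cfg$downstream_intron_log10[2])
  ilen <- as.integer(round(10^stats::rnorm(length(gi), ln_mean, ln_sd)))
  ilen <- pmin(ilen, 20000L)
  ilen[is_first] <- pmax(ilen[is_first], 400L)
  ilen[!is_first] <- pmax(ilen[!is_first], 170L)
  # RS introns need room for internal sites >= 75 nt from both ends
  ilen[is_rs] <- pmax(ilen[is_rs], 240L)
  if (any(is_rs & ilen < 150L)) stop("recursive site assigned to an intron shorter than 150 nt")

  rs_class <- rep("basic", length(gi))
  rs_class[is_rs] <- sample(names(cfg$rs_class_probs), sum(is_rs), replace = TRUE,
                            prob = cfg$rs_class_probs)

  elen_list <- lapply(m + 1L, function(k) sample(seq.int(cfg$exon_length_range[1],
                                                         cfg$exon_length_range[2]), k, replace = TRUE))

  # genome layout ------------------------------------------------------------
  chrom_of <- paste0("chr", (seq_len(n) - 1L) %/% cfg$genes_per_chrom + 1L)
  glen <- vapply(seq_len(n), function(g) sum(elen_list[[g]]) + sum(ilen[gi == g]), 0)
  gstart <- integer(n)
  off <- stats::setNames(rep(0L, length(unique(chrom_of))), unique(chrom_of))
  for (g in seq_len(n)) {
    gstart[g] <- off[chrom_of[g]] + cfg$intergenic_gap + 1L
    off[chrom_of[g]] <- gstart[g] + as.integer(glen[g]) - 1L
  }
  chrom_len <- off + cfg$intergenic_gap
  bases <- names(cfg$background_base_probs)

  site_rows <- vector("list", n)
  chromvec <- lapply(chrom_len, function(L) sample(bases, L, replace = TRUE,
                                                   prob = cfg$background_base_probs))

  ppt_rs_probs <- (1 - cfg$ppt_purine_dilution) * cfg$ppt_base_probs +
    cfg$ppt_purine_dilution * c(A = 0.28, C = 0.12, G = 0.05, T = 0.55)

  # transcription-local 0-based starts of exons/introns, per gene
  ex_start_list <- vector("list", n)
  in_start_list <- vector("list", n)
  for (g in seq_len(n)) {
    mg <- m[g]
    seg_len <- as.integer(rbind(elen_list[[g]], c(ilen[gi == g], NA))[seq_len(2L * mg + 1L)])
    seg_start <- cumsum(c(0L, seg_len[-length(seg_len)]))
    ex_start_list[[g]] <- seg_start[seq(1L, 2L * mg + 1L, by = 2L)]
    in_start_list[[g]] <- seg_start[seq(2L, 2L * mg, by = 2L)]
  }

  for (g in seq_len(n)) {
    mg <- m[g]
    el <- elen_list[[g]]
    il <- ilen[gi == g]
    cls <- rs_class[gi == g]
    ex_start_t <- ex_start_list[[g]]
    in_start_t <- in_start_list[[g]]
    L <- sum(el) + sum(il)
    gs <- gstart[g]; ge <- gs + L - 1L
    tog <- if (strand[g] == "+") function(t) gs + t else function(t) ge - t
    cv <- chrom_of[g]
    # local plant: write sense-strand `chars` at transcription positions t0..;
    # minus-strand genes store the reverse complement on the genomic strand
    plant <- function(t0, chars) {
      tt <- t0 + seq_along(chars) - 1L
      if (strand[g] == "+") {
        chromvec[[cv]][gs + tt] <<- chars
      } else {
        chromvec[[cv]][sort(ge - tt)] <<- revcomp_chars(chars)
      }
    }
    # CG-rich motif flanking the first-intron 5'SS of RS genes
    if (first_rs[g] && cfg$cg_motif_strength > 0) {
      w <- in_start_t[1L] + cfg$cg_window[1]:cfg$cg_window[2]
      w <- w[w >= 0L & w < L]
      cur <- if (strand[g] == "+") {
        chromvec[[cv]][gs + w]
      } else {
        revcomp_chars(chromvec[[cv]][sort(ge - w)])
      }
      plant(w[1L], plant_cg_chars(cur, cfg$cg_motif_strength))
    }
    # polypyrimidine tract upstream of the first-intron 3'SS
    ppt <- if (first_rs[g]) ppt_rs_probs else cfg$ppt_base_probs
    p3 <- in_start_t[1L] + il[1L] - 1L     # local position of last intron base
    wlen <- cfg$ppt_window[2] - cfg$ppt_window[1] + 1L
    plant(p3 + cfg$ppt_window[1], sample(bases, wlen, replace = TRUE, prob = ppt))

    # recursive sites + junction-local coordinates
    for (j in seq_len(mg)) {
      if (cls[j] == "basic") next
      it <- in_start_t[j]; Lj <- il[j]
      lo <- 75L; hi <- Lj - 76L
      nst <- cfg$n_recursive_sites
      if (cls[j] == "nested") {
        d5 <- lo + sample.int(hi - 30L - lo + 1L, 1L) - 1L
        d3 <- d5 + 30L + sample.int(hi - d5 - 30L + 1L, 1L) - 1L
        sites <- data.frame(junction = 1L, d5 = d5, d3 = d3)
      } else {
        dd <- integer(0)
        tries <- 0L
        while (length(dd) < nst && tries < 100L) {
          d <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          if (all(abs(dd - d) >= 8L)) dd <- c(dd, d)
          tries <- tries + 1L
        }
        sites <- if (cls[j] == "RS5") {
          data.frame(junction = seq_along(dd), d5 = dd, d3 = NA_integer_)
        } else {
          data.frame(junction = seq_along(dd), d5 = NA_integer_, d3 = dd)
        }
      }
      sites$intact5 <- !is.na(sites$d5) & stats::runif(nrow(sites)) >= cfg$aggu_degraded_fraction
      sites$intact3 <- !is.na(sites$d3) & stats::runif(nrow(sites)) >= cfg$aggu_degraded_fraction
      aggu <- c("A", "G", "G", "T")
      for (s in seq_len(nrow(sites))) {
        if (sites$intact5[s]) plant(it + sites$d5[s] - 2L, aggu)
        if (sites$intact3[s]) plant(it + sites$d3[s] - 1L, aggu)
      }
      # genomic coordinates of junctions and recursive sites (vectorized)
      a <- ifelse(is.na(sites$d5), 0L, sites$d5)
      b <- ifelse(is.na(sites$d3), Lj - 1L, sites$d3)
      ga <- tog(it + a); gb <- tog(it + b)
      site_rows[[g]][[j]] <- data.table::data.table(
        gene = g, intron_rank = j, rs_class = cls[j],
        start = pmin(ga, gb), end = pmax(ga, gb),
        rec5 = ifelse(is.na(sites$d5), NA_integer_, tog(it + sites$d5)),
        rec3 = ifelse(is.na(sites$d3), NA_integer_, tog(it + sites$d3)),
        intact5 = sites$intact5, intact3 = sites$intact3,
        has5 = !is.na(sites$d5), has3 = !is.na(sites$d3))
    }
    # canonical boundaries stamped last so splice sites are always GT..AG
    for (j in seq_len(mg)) {
      plant(in_start_t[j], c("G", "T"))
      plant(in_start_t[j] + il[j] - 2L, c("A", "G"))
    }
  }

  # genomic exon/intron records (vectorized over all genes)
  ex_t0 <- unlist(ex_start_list, use.names = FALSE)
  ex_len <- unlist(elen_list, use.names = FALSE)
  ex_gi <- rep.int(seq_len(n), m + 1L)
  gmap <- function(gidx, t) {
    # genomic coordinate of transcription-local position t
    ifelse(strand[gidx] == "+", gstart[gidx] + t,
           gstart[gidx] + as.integer(glen[gidx]) - 1L - t)
  }
  ex_a <- gmap(ex_gi, ex_t0); ex_b <- gmap(ex_gi, ex_t0 + ex_len - 1L)
  exons <- data.frame(gene_id = gene_id[ex_gi], transcript_id = transcript_id[ex_gi],
                      chrom = chrom_of[ex_gi], start = pmin(ex_a, ex_b),
                      end = pmax(ex_a, ex_b), strand = strand[ex_gi],
                      stringsAsFactors = FALSE)
  in_t0 <- unlist(in_start_list, use.names = FALSE)
  in_a <- gmap(gi, in_t0); in_b <- gmap(gi, in_t0 + ilen - 1L)
  truth_introns <- data.table::data.table(
    gene_id = gene_id[gi], transcript_id = transcript_id[gi],
    chrom = chrom_of[gi], start = pmin(in_a, in_b), end = pmax(in_a, in_b),
    strand = strand[gi], intron_rank = rank, is_rs = is_rs, rs_class = rs_class)

  annotation <- genome_annotation(exons)
  genome <- Biostrings::DNAStringSet(vapply(chromvec, paste, "", collapse = ""))
  names(genome) <- names(chrom_len)

  truth_introns[, position_class := ifelse(intron_rank == 1L, "first",
                                    ifelse(intron_rank == ave(intron_rank, gene_id, FUN = max),
                                           "last", "middle"))]
  site_dt <- data.table::rbindlist(unlist(site_rows, recursive = FALSE))
  if (nrow(site_dt) > 0L) {
    site_dt[, `:=`(gene_id = gene_id[gene], transcript_id = transcript_id[gene],
                   chrom = chrom_of[gene], strand = strand[gene])]
    site_dt[, gene := NULL]
  } else {
    site_dt <- data.table::data.table(
      intron_rank = integer(0), rs_class = character(0), start = integer(0),
      end = integer(0), rec5 = integer(0), rec3 = integer(0),
      intact5 = logical(0), intact3 = logical(0), has5 = logical(0),
      has3 = logical(0), gene_id = character(0), transcript_id = character(0),
      chrom = character(0), strand = character(0))
  }

  # junction tables ----------------------------------------------------------
  can <- data.table::as.data.table(annotation$introns)[, .(chrom, start, end, strand)]
  rec <- site_dt[, .(chrom, start, end, strand)]
  nascent <- lapply(seq_len(cfg$n_nascent_samples), function(s) {
    jt <- rbind(cbind(can, annotated = TRUE), if (nrow(rec) > 0L) cbind(rec, annotated = FALSE))
    jt[, unique_reads := rnb_pos(.N, cfg$read_count_mean, cfg$read_count_dispersion)]
    jt[, multimap_reads := stats::rbinom(.N, 3L, 0.3)]
    if (cfg$noise_junction_fraction > 0) {
      nn <- max(0L, round(cfg$noise_junction_fraction * nrow(jt)))
      if (nn > 0L) {
        gsel <- sample.int(n, nn, replace = TRUE)
        ns <- pmax(1L, gstart[gsel] - cfg$intergenic_gap + 5L)
        jt <- rbind(jt, data.table::data.table(
          chrom = chrom_of[gsel], start = ns, end = ns + 60L,
          strand = sample(c("+", "-"), nn, TRUE), annotated = FALSE,
          unique_reads = rnb_pos(nn, cfg$read_count_mean, cfg$read_count_dispersion),
          multimap_reads = 0L))
      }
    }
    jt[, phase := "nascent"]
    jt[, sample_id := paste0("nascent_", s)]
    data.table::setDF(jt)
  })
  mature <- {
    jt <- cbind(data.table::copy(can), annotated = TRUE)
    jt[, unique_reads := rnb_pos(.N, cfg$read_count_mean * 2, cfg$read_count_dispersion)]
    jt[, multimap_reads := stats::rbinom(.N, 3L, 0.3)]
    jt[, phase := "mature"]
    jt[, sample_id := "mature_1"]
    data.table::setDF(jt)
  }

  # expression ---------------------------------------------------------------
  tpm <- data.frame(transcript_id = transcript_id, gene_id = gene_id,
                    TPM = round(10^stats::rnorm(n, cfg$tpm_log10[1] +
                                                  cfg$tpm_rs_log10_shift * first_rs,
                                                cfg$tpm_log10[2]), 3))

  # methylation: CpGs of every exon; first-exon level set by RS status -------
  exd <- data.table::as.data.table(annotation$exons)
  exd[, exon_seq := as.character(Biostrings::DNAStringSet(genome[exd$chrom],
                                                          start = exd$start, end = exd$end))]
  first_rs_of <- stats::setNames(first_rs, gene_id)
  down_of <- stats::setNames(down_any, gene_id)
  hits <- gregexpr("CG", exd$exon_seq, fixed = TRUE)
  ncpg <- vapply(hits, function(h) if (h[1L] == -1L) 0L else length(h), 0L)
  ab_first <- ifelse(first_rs_of[exd$gene_id], 1L, ifelse(down_of[exd$gene_id], 2L, 3L))
  ab_idx <- ifelse(exd$exon_rank == 1L, ab_first, 3L)
  ab_tab <- rbind(cfg$methylation_beta_rs, cfg$methylation_beta_down,
                  cfg$methylation_beta_basic)
  mu <- stats::rbeta(nrow(exd), ab_tab[ab_idx, 1L], ab_tab[ab_idx, 2L])
  ei <- rep.int(seq_len(nrow(exd)), ncpg)
  gpos <- exd$start[ei] + unlist(lapply(hits, function(h) if (h[1L] == -1L) integer(0)
                                        else as.integer(h)), use.names = FALSE) - 1L
  pct <- pmin(100, pmax(0, 100 * mu[ei] + stats::rnorm(length(gpos), 0, 8)))
  plus <- data.table::data.table(chrom = exd$chrom[ei], position = gpos, strand = "+",
                                 coverage = rnb_pos(length(gpos), 30, 0.1),
                                 percent_methylated = round(pct, 2))
  minus_sel <- stats::runif(length(gpos)) < 0.5
  minus <- data.table::data.table(
    chrom = exd$chrom[ei][minus_sel], position = gpos[minus_sel] + 1L, strand = "-",
    coverage = rnb_pos(sum(minus_sel), 30, 0.1),
    percent_methylated = round(pmin(100, pmax(0, pct[minus_sel] +
                                              stats::rnorm(sum(minus_sel), 0, 3))), 2))
  methylation <- data.table::setDF(rbind(plus, minus))
  data.table::setorderv(methylation, c("chrom", "position"))

  # RBNS: baseline R = 1 with a CG-preferring and a pyrimidine-preferring
  # pseudo-protein at two concentrations each -------------------------------
  kmers <- all_kmers(cfg$rbns_k)
  n_cg <- vapply(kmers, function(x) {
    sum(gregexpr("CG", x, fixed = TRUE)[[1L]] > 0L)
  }, 0L)
  n_py <- vapply(strsplit(kmers, ""), function(ch) sum(ch %in% c("C", "T")), 0L)
  rbns <- data.table::rbindlist(list(
    data.table::data.table(protein = "CGBP1", concentration = 5,
                           kmer = kmers, R = exp(0.25 * n_cg + stats::rnorm(length(kmers), 0, 0.05))),
    data.table::data.table(protein = "CGBP1", concentration = 20,
                           kmer = kmers, R = exp(0.5 * n_cg + stats::rnorm(length(kmers), 0, 0.05))),
    data.table::data.table(protein = "PYBP1", concentration = 5,
                           kmer = kmers, R = exp(0.15 * (n_py - cfg$rbns_k / 2) + stats::rnorm(length(kmers), 0, 0.05))),
    data.table::data.table(protein = "PYBP1", concentration = 20,
                           kmer = kmers, R = exp(0.3 * (n_py - cfg$rbns_k / 2) + stats::rnorm(length(kmers), 0, 0.05))),
    data.table::data.table(protein = "NEUT1", concentration = 5,
                           kmer = kmers, R = exp(stats::rnorm(length(kmers), 0, 0.05))),
    data.table::data.table(protein = "NEUT1", concentration = 20,
                           kmer = kmers, R = exp(stats::rnorm(length(kmers), 0, 0.05)))))
  rbns[, R := round(R, 6)]
  rbns <- data.table::setDF(rbns)

  truth_transcripts <- data.frame(gene_id = gene_id, transcript_id = transcript_id,
                                  n_introns = m, first_rs = first_rs,
                                  downstream_rs = down_any, TPM = tpm$TPM)
  bundle <- list(annotation = annotation, genome = genome, nascent = nascent,
                 mature = mature, tpm = tpm, methylation = methylation, rbns = rbns,
                 truth = list(introns = data.table::setDF(truth_introns),
                              sites = data.table::setDF(site_dt),
                              transcripts = truth_transcripts),
                 config = cfg)
  if (!is.null(dir)) bundle$paths <- write_bundle(bundle, dir)
  bundle
}

# write every bundle component in the dialect io_formats reads
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "annotation.gtf"),
    nascent = file.path(dir, sprintf("nascent_%d.SJ.out.tab", seq_along(bundle$nascent))),
    mature = file.path(dir, "mature_1.SJ.out.tab"),
    tpm = file.path(dir, "tpm.tsv"),
    methylation = file.path(dir, "methylation.bed"),
    rbns = file.path(dir, "rbns.tsv"),
    truth_introns = file.path(dir, "truth_introns.tsv"),
    truth_sites = file.path(dir, "truth_sites.tsv"),
    truth_transcripts = file.path(dir, "truth_transcripts.tsv"),
    config = file.path(dir, "config.txt"))
  Biostrings::writeXStringSet(bundle$genome, paths$genome)
  ex <- bundle$annotation$exons
  gtf <- data.table::data.table(
    chrom = ex$chrom, source = "recsplice_synth", feature = "exon",
    start = ex$start, end = ex$end, score = ".", strand = ex$strand, frame = ".",
    attributes = sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id, ex$transcript_id))
  data.table::fwrite(gtf, paths$gtf, sep = "\t", col.names = FALSE, quote = FALSE)
  for (i in seq_along(bundle$nascent)) write_sj_table(bundle$nascent[[i]], paths$nascent[i])
  write_sj_table(bundle$mature, paths$mature)
  data.table::fwrite(bundle$tpm, paths$tpm, sep = "\t")
  write_bedmethyl(bundle$methylation, paths$methylation)
  data.table::fwrite(bundle$rbns, paths$rbns, sep = "\t")
  data.table::fwrite(bundle$truth$introns, paths$truth_introns, sep = "\t")
  data.table::fwrite(bundle$truth$sites, paths$truth_sites, sep = "\t")
  data.table::fwrite(bundle$truth$transcripts, paths$truth_transcripts, sep = "\t")
  write_synthetic_config(bundle$config, paths$config)
  paths
}

#' Write / read a synthetic configuration as key = value text
#' @param config a [synthetic_config()].
#' @param path file path.
#' @export
write_synthetic_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    vals <- if (!is.null(names(v)) && any(nzchar(names(v)))) {
      paste(names(v), unname(v), sep = ":", collapse = ",")
    } else paste(v, collapse = ",")
    paste0(k, " = ", vals)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  vals <- lapply(kv, function(x) {
    parts <- strsplit(x[2L], ",", fixed = TRUE)[[1L]]
    if (all(grepl(":", parts, fixed = TRUE))) {
      nm <- sub(":.*$", "", parts)
      v <- sub("^[^:]*:", "", parts)
      num <- suppressWarnings(as.numeric(v))
      stats::setNames(if (anyNA(num)) v else num, nm)
    } else {
      num <- suppressWarnings(as.numeric(parts))
      if (anyNA(num)) {
        if (all(parts %in% c("TRUE", "FALSE"))) as.logical(parts) else parts
      } else num
    }
  })
  names(vals) <- vapply(kv, `[`, "", 1L)
  int_fields <- c("n_genes", "introns_per_gene", "exon_length_range", "n_recursive_sites",
                  "rbns_k", "n_nascent_samples", "genes_per_chrom", "intergenic_gap",
                  "seed", "cg_window", "ppt_window")
  for (f in intersect(int_fields, names(vals))) vals[[f]] <- as.integer(vals[[f]])
  do.call(synthetic_config, vals)
}
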