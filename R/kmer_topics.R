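# Positional k-mer counting and latent Dirichlet allocation topic models ----

#' All k-mers over the DNA alphabet, in lexicographic (ACGT) order
#' @param k k-mer length.
#' @return character vector of length `4^k`, matching the column order of
#'   [Biostrings::oligonucleotideFrequency()].
#' @export
all_kmers <- function(k) Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)

#' Extract splice-site flanking sequences in transcription orientation
#'
#' Anchors position 0 at the first intron base (5' sites) or the last intron
#' base (3' sites); recursive sites are anchored on the recursive coordinate
#' reported by [classify_junctions()]. Minus-strand windows are
#' reverse-complemented so position always increases 5' to 3'. Sites whose
#' window is truncated by a contig edge are dropped.
#'
#' @param classified result of [classify_junctions()] (or a data.frame of
#'   introns with `rs_class` and `position_class` columns for canonical
#'   sites).
#' @param genome DNAStringSet.
#' @param site_type one of `canonical5`, `canonical3`, `recursive5`,
#'   `recursive3`.
#' @param window `c(lo, hi)` offsets; defaults: -30..+50 for 5' sites,
#'   -50..+30 for 3' sites.
#' @return data.frame with `site_id`, `site_type`, `rs_class`,
#'   `intron_position` (`first`/`downstream`) and `sequence`; the window is
#'   attached as attribute `window`.
#' @export
extract_site_sequences <- function(classified, genome, site_type, window = NULL) {
  site_type <- match.arg(site_type, c("canonical5", "canonical3", "recursive5", "recursive3"))
  if (is.null(window)) {
    window <- if (site_type %in% c("canonical5", "recursive5")) c(-30L, 50L) else c(-50L, 30L)
  }
  tab <- if (is.data.frame(classified)) classified
         else if (site_type %in% c("canonical5", "canonical3")) classified$introns
         else classified$junctions
  dt <- data.table::as.data.table(tab)
  if (nrow(dt) == 0L) {
    out <- data.frame(site_id = character(0), site_type = character(0),
                      rs_class = character(0), intron_position = character(0),
                      sequence = character(0))
    attr(out, "window") <- window
    return(out)
  }
  pos <- switch(site_type,
    canonical5 = ifelse(dt$strand == "+", dt$start, dt$end),
    canonical3 = ifelse(dt$strand == "+", dt$end, dt$start),
    recursive5 = dt$recursive_5ss,
    recursive3 = dt$recursive_3ss)
  keep <- !is.na(pos)
  dt <- dt[keep]; pos <- pos[keep]
  seqs <- extract_window(genome, dt$chrom, pos, dt$strand, window)
  ipos <- if ("position_class" %in% names(dt)) {
    ifelse(dt$position_class == "first", "first", "downstream")
  } else rep("first", nrow(dt))
  out <- data.frame(site_id = paste(dt$chrom, pos, dt$strand, sep = ":"),
                    site_type = site_type,
                    rs_class = if ("rs_class" %in% names(dt)) dt$rs_class else "basic",
                    intron_position = ipos, sequence = seqs,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$sequence), , drop = FALSE]
  attr(out, "window") <- window
  out
}

#' Sample pseudo-recursive AGGU occurrences inside introns
#'
#' Uniformly samples internal sense-strand AGGT occurrences (the DNA form of
#' the AGGU ratchet) at least `min_distance` from both annotated splice
#' sites, as background contrasts for true recursive sites. The site
#' coordinate is the G of the GU half (the would-be recursive 5'SS).
#'
#' @param introns data.frame of introns (>= 150 nt are eligible).
#' @param genome DNAStringSet.
#' @param n maximum number of sites to draw.
#' @param min_distance minimum distance from both annotated splice sites.
#' @param window flanking window for the returned sequences (default -30..+50).
#' @param seed RNG seed.
#' @return data.frame in the layout of [extract_site_sequences()] with
#'   `site_type = "pseudoAGGU"`.
#' @export
sample_pseudo_aggu <- function(introns, genome, n, min_distance = 75L,
                               window = c(-30L, 50L), seed = 1L) {
  dt <- data.table::as.data.table(introns)
  dt <- dt[end - start + 1L >= 150L]
  hits <- data.table::data.table()
  if (nrow(dt) > 0L) {
    iseq <- extract_window(genome, dt$chrom,
                           ifelse(dt$strand == "+", dt$start, dt$end),
                           dt$strand, c(0L, max(dt$end - dt$start)))
    # per intron, restrict to its own length (the batched window over-reads)
    rows <- lapply(seq_len(nrow(dt)), function(i) {
      L <- dt$end[i] - dt$start[i] + 1L
      s <- substr(iseq[i], 1L, L)
      if (is.na(s)) return(NULL)
      occ <- gregexpr("AGGT", s, fixed = TRUE)[[1L]]
      if (occ[1L] == -1L) return(NULL)
      site_off <- as.integer(occ) + 1L   # 0-based offset of the G of GT
      ok <- site_off >= min_distance & (L - 1L - site_off) >= min_distance
      if (!any(ok)) return(NULL)
      data.table::data.table(row = i, offset = site_off[ok])
    })
    hits <- data.table::rbindlist(rows)
  }
  if (nrow(hits) == 0L) {
    warning("no eligible internal AGGT occurrences found")
    out <- data.frame(site_id = character(0), site_type = character(0),
                      rs_class = character(0), intron_position = character(0),
                      sequence = character(0))
    attr(out, "window") <- window
    return(out)
  }
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  take <- hits[sample.int(nrow(hits), min(n, nrow(hits)))]
  sub <- dt[take$row]
  gpos <- ifelse(sub$strand == "+", sub$start + take$offset, sub$end - take$offset)
  seqs <- extract_window(genome, sub$chrom, gpos, sub$strand, window)
  ipos <- if ("position_class" %in% names(sub)) {
    ifelse(sub$position_class == "first", "first", "downstream")
  } else rep("first", nrow(sub))
  out <- data.frame(site_id = paste(sub$chrom, gpos, sub$strand, sep = ":"),
                    site_type = "pseudoAGGU",
                    rs_class = if ("rs_class" %in% names(sub)) sub$rs_class else "basic",
                    intron_position = ipos, sequence = seqs,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$sequence), , drop = FALSE]
  attr(out, "window") <- window
  out
}

# integer k-mer ids at every start of every sequence: list(starts x seq matrix)
kmer_id_matrix <- function(seqs, k) {
  vocab <- all_kmers(k)
  W <- unique(nchar(seqs))
  if (length(W) != 1L) stop("all sequences must share one window length")
  n_start <- W - k + 1L
  ids <- vapply(seq_len(n_start), function(s) {
    match(substr(seqs, s, s + k - 1L), vocab)
  }, integer(length(seqs)))
  if (length(seqs) == 1L) ids <- matrix(ids, nrow = 1L)
  ids   # n_seq x n_start
}

#' Positional k-mer count matrix around splice sites
#'
#' One document per (site_type, rs_class, position p); its counts are the
#' k-mers whose start offsets fall in `[p, p + window_smooth - 1]`, summed
#' over all sequences of the subtype. Positions whose smoothing window would
#' run past the last k-mer start are truncated from the document set.
#'
#' @param site_sequences data.frame from [extract_site_sequences()] (all one
#'   window).
#' @param k k-mer length (default 4, tetramers).
#' @param window_smooth sliding-window width in bp (default 6).
#' @param window offsets of the sequence window; taken from the input's
#'   `window` attribute when present, else positions are 0-based sequence
#'   offsets.
#' @return an object of class `kmer_counts`: list with `counts`
#'   (documents x 4^k), `docs` metadata, `k`, `vocab`, `smooth`.
#' @export
positional_kmer_matrix <- function(site_sequences, k = 4L, window_smooth = 6L,
                                   window = attr(site_sequences, "window")) {
  seqs <- site_sequences$sequence
  if (length(seqs) == 0L) stop("no sequences")
  W <- unique(nchar(seqs))
  if (length(W) != 1L) stop("all sequences must share one window length")
  lo <- if (is.null(window)) 0L else window[1L]
  n_start <- W - k + 1L
  n_doc <- n_start - window_smooth + 1L
  if (n_doc < 1L) stop("window_smooth larger than the number of k-mer starts")
  vocab <- all_kmers(k)
  subtype <- interaction(site_sequences$site_type, site_sequences$rs_class,
                         drop = TRUE, sep = "|")
  mats <- list(); metas <- list()
  for (st in levels(subtype)) {
    sel <- which(subtype == st)
    ids <- kmer_id_matrix(seqs[sel], k)
    # counts per start position
    start_counts <- vapply(seq_len(n_start), function(s) {
      tabulate(ids[, s], nbins = length(vocab))
    }, numeric(length(vocab)))            # V x n_start
    cs <- cbind(0, t(apply(start_counts, 1L, cumsum)))  # V x (n_start+1)
    doc <- t(cs[, (window_smooth + 1L):(n_start + 1L), drop = FALSE] -
             cs[, 1L:n_doc, drop = FALSE])               # n_doc x V
    parts <- strsplit(st, "|", fixed = TRUE)[[1L]]
    mats[[st]] <- doc
    metas[[st]] <- data.frame(site_type = parts[1L], rs_class = parts[2L],
                              position = lo + seq_len(n_doc) - 1L,
                              stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, mats)
  docs <- do.call(rbind, metas)
  rownames(counts) <- paste(docs$site_type, docs$rs_class, docs$position, sep = "|")
  colnames(counts) <- vocab
  rownames(docs) <- NULL
  structure(list(counts = counts, docs = docs, k = k, vocab = vocab,
                 smooth = window_smooth), class = "kmer_counts")
}

#' Grouped per-sequence k-mer count matrix
#'
#' Sequences of each subtype (site_type x rs_class x intron_position) are
#' shuffled (seeded), partitioned into disjoint groups of `group_size`, and
#' each group's overlapping k-mer counts over the whole window are summed
#' into one document. Remainders are dropped; subtypes smaller than
#' `group_size` are skipped with a warning.
#'
#' @inheritParams positional_kmer_matrix
#' @param group_size sequences per document (default 15).
#' @param seed shuffle seed.
#' @return a `kmer_counts` object; `docs` carries the subtype and group index.
#' @export
grouped_kmer_matrix <- function(site_sequences, group_size = 15L, k = 4L, seed = 1L) {
  seqs <- site_sequences$sequence
  if (length(seqs) == 0L) stop("no sequences")
  vocab <- all_kmers(k)
  subtype <- interaction(site_sequences$site_type, site_sequences$rs_class,
                         site_sequences$intron_position, drop = TRUE, sep = "|")
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  per_seq <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs), width = k)
  mats <- list(); metas <- list()
  for (st in levels(subtype)) {
    sel <- which(subtype == st)
    if (length(sel) < group_size) {
      warning("subtype ", st, " has fewer than ", group_size, " sequences; skipped")
      next
    }
    sel <- sel[sample.int(length(sel))]
    ng <- length(sel) %/% group_size
    sel <- sel[seq_len(ng * group_size)]
    grp <- rep(seq_len(ng), each = group_size)
    gm <- rowsum(per_seq[sel, , drop = FALSE], grp)
    parts <- strsplit(st, "|", fixed = TRUE)[[1L]]
    mats[[st]] <- gm
    metas[[st]] <- data.frame(site_type = parts[1L], rs_class = parts[2L],
                              intron_position = parts[3L], group = seq_len(ng),
                              stringsAsFactors = FALSE)
  }
  if (length(mats) == 0L) stop("no subtype had at least group_size sequences")
  counts <- do.call(rbind, mats)
  docs <- do.call(rbind, metas)
  rownames(counts) <- paste(docs$site_type, docs$rs_class, docs$intron_position,
                            docs$group, sep = "|")
  colnames(counts) <- vocab
  rownames(docs) <- NULL
  structure(list(counts = counts, docs = docs, k = k, vocab = vocab,
                 smooth = NA_integer_), class = "kmer_counts")
}

# --- batch variational-Bayes LDA -------------------------------------------

dirichlet_expectation <- function(a) {
  if (is.matrix(a)) digamma(a) - digamma(rowSums(a)) else digamma(a) - digamma(sum(a))
}

# E-step over all documents simultaneously; returns gamma and the sufficient
# statistics for lambda
lda_estep <- function(X, expElogbeta, alpha, max_inner = 100L, inner_tol = 1e-3) {
  D <- nrow(X); K <- nrow(expElogbeta)
  gamma <- matrix(stats::rgamma(D * K, 100, 100), D, K)
  expElogtheta <- exp(dirichlet_expectation(gamma))
  phinorm <- expElogtheta %*% expElogbeta + 1e-100
  for (it in seq_len(max_inner)) {
    last <- gamma
    gamma <- alpha + expElogtheta * ((X / phinorm) %*% t(expElogbeta))
    expElogtheta <- exp(dirichlet_expectation(gamma))
    phinorm <- expElogtheta %*% expElogbeta + 1e-100
    if (mean(abs(gamma - last)) < inner_tol) break
  }
  sstats <- t(expElogtheta) %*% (X / phinorm)   # K x V, to be * expElogbeta
  list(gamma = gamma, sstats = sstats, phinorm = phinorm)
}

#' Fit a latent Dirichlet allocation mixture model to k-mer counts
#'
#' Batch variational-Bayes LDA with symmetric priors (document-topic prior
#' `1/n_topics`, topic-word prior `1/4^k`). The fit is deterministic given
#' `seed`. Returns row-stochastic topic-by-k-mer probabilities and
#' document-by-topic memberships (grades of membership).
#'
#' @param x a `kmer_counts` object or a non-negative count matrix with k-mer
#'   columns.
#' @param n_topics number of topics (default 6).
#' @param seed RNG seed (mandatory for reproducibility).
#' @param max_iter,tol outer variational-EM iteration cap and convergence
#'   tolerance on the mean per-row L1 change of the topic matrix.
#' @return object of class `rs_topic_model` with `topics` (n_topics x 4^k),
#'   `memberships` (documents x n_topics), `log_likelihood` trace, `docs`
#'   metadata (when available), `vocab`, `seed`.
#' @export
fit_mixture <- function(x, n_topics = 6L, seed = 1L, max_iter = 500L, tol = 1e-3) {
  X <- if (inherits(x, "kmer_counts")) x$counts else as.matrix(x)
  docs <- if (inherits(x, "kmer_counts")) x$docs else NULL
  if (n_topics < 2L) stop("n_topics must be >= 2")
  if (any(X < 0)) stop("counts must be non-negative")
  zero <- rowSums(X) == 0
  if (any(zero)) stop(sum(zero), " all-zero document(s); remove before fitting")
  if (nrow(X) < n_topics) stop("need at least n_topics documents")
  V <- ncol(X); K <- n_topics
  alpha <- 1 / K; eta <- 1 / V
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  lambda <- matrix(stats::rgamma(K * V, 100, 100), K, V)
  expElogbeta <- exp(dirichlet_expectation(lambda))
  ll <- numeric(0)
  beta_prev <- lambda / rowSums(lambda)
  for (it in seq_len(max_iter)) {
    es <- lda_estep(X, expElogbeta, alpha)
    lambda <- eta + es$sstats * expElogbeta
    expElogbeta <- exp(dirichlet_expectation(lambda))
    ll <- c(ll, sum(X * log(es$phinorm)) / sum(X))
    beta <- lambda / rowSums(lambda)
    delta <- mean(rowSums(abs(beta - beta_prev)))
    beta_prev <- beta
    if (delta < tol) break
  }
  # final E-step so memberships are consistent with the final topics
  es <- lda_estep(X, expElogbeta, alpha)
  memberships <- es$gamma / rowSums(es$gamma)
  topics <- lambda / rowSums(lambda)
  rownames(topics) <- paste0("topic", seq_len(K))
  colnames(topics) <- colnames(X)
  colnames(memberships) <- rownames(topics)
  rownames(memberships) <- rownames(X)
  structure(list(topics = topics, memberships = memberships,
                 log_likelihood = ll, docs = docs, vocab = colnames(X),
                 n_topics = K, alpha = alpha, eta = eta, seed = seed,
                 n_iter = length(ll), lambda = lambda),
            class = "rs_topic_model")
}

#' @export
print.rs_topic_model <- function(x, ...) {
  cat(sprintf("rs_topic_model: %d topics x %d k-mers, %d documents, %d VB iterations\n",
              x$n_topics, length(x$vocab), nrow(x$memberships), x$n_iter))
  invisible(x)
}

#' Posterior topic expectations for new count vectors
#'
#' Held-out inference: the topic matrix is fixed and the variational
#' document-topic posterior is computed for each new count row.
#'
#' @param model a fitted [fit_mixture()] model.
#' @param new_counts a `kmer_counts` object or count matrix over the same
#'   vocabulary.
#' @return matrix (documents x topics), rows summing to 1.
#' @export
topic_expectations <- function(model, new_counts) {
  stopifnot(inherits(model, "rs_topic_model"))
  X <- if (inherits(new_counts, "kmer_counts")) new_counts$counts else as.matrix(new_counts)
  if (ncol(X) != length(model$vocab) ||
      (!is.null(colnames(X)) && !identical(colnames(X), model$vocab))) {
    stop("vocabulary mismatch between model and new counts")
  }
  if (any(rowSums(X) == 0)) stop("all-zero count vector(s) rejected")
  expElogbeta <- exp(dirichlet_expectation(model$lambda))
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(model$seed)
  es <- lda_estep(X, expElogbeta, model$alpha)
  memb <- es$gamma / rowSums(es$gamma)
  colnames(memb) <- rownames(model$topics)
  rownames(memb) <- rownames(X)
  memb
}

#' Driving k-mers of each topic by Poisson Kullback-Leibler divergence
#'
#' For topic t and k-mer w with probability `p` in the topic and mean
#' probability `q` over all other topics, the distinctiveness score is
#' `p * ln(p/q) + q - p` (the KL divergence of Poisson rates), floored at a
#' pseudo-probability of 1e-10. K-mers are ranked descending within topic.
#'
#' @param model a fitted [fit_mixture()] model.
#' @return data.frame `topic`, `kmer`, `kl_score`, `rank`.
#' @export
driving_kmers <- function(model) {
  stopifnot(inherits(model, "rs_topic_model"))
  K <- model$n_topics
  if (K < 2L) stop("need at least 2 topics")
  beta <- pmax(model$topics, 1e-10)
  rows <- lapply(seq_len(K), function(t) {
    p <- beta[t, ]
    q <- pmax(colMeans(beta[-t, , drop = FALSE]), 1e-10)
    score <- p * log(p / q) + q - p
    ord <- order(-score, names(score))
    data.frame(topic = rownames(beta)[t], kmer = names(score)[ord],
               kl_score = unname(score[ord]), rank = seq_along(score),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
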