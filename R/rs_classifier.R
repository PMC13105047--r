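# Feature assembly and random-forest classification of RS outcome ------------

# the four sequence regions feeding the topic features
rs_regions <- c("upstream_exon", "intron_5p", "intron_3p", "downstream_exon")

# per-intron sequences of the four regions (exons truncated to `exon_trunc`
# nt at the splice-site-proximal end); NA where a region is unavailable
region_sequences <- function(introns, annotation, genome, exon_trunc = 300L) {
  ci <- data.table::as.data.table(introns)
  fl <- flanking_exons(ci, annotation)
  clip_prox <- function(iv, keep_end) {
    # keep the `exon_trunc` bases nearest the intron
    len <- iv$end - iv$start + 1L
    over <- !is.na(len) & len > exon_trunc
    s <- iv$start; e <- iv$end
    s[over & keep_end == "right"] <- e[over & keep_end == "right"] - exon_trunc + 1L
    e[over & keep_end == "left"] <- s[over & keep_end == "left"] + exon_trunc - 1L
    list(start = s, end = e)
  }
  getseq <- function(start, end, flip_for_minus = TRUE) {
    out <- rep(NA_character_, nrow(ci))
    ok <- !is.na(start) & !is.na(end) & end >= start
    if (!any(ok)) return(out)
    ss <- Biostrings::DNAStringSet(genome[ci$chrom[ok]], start = start[ok], end = end[ok])
    neg <- ci$strand[ok] == "-"
    if (any(neg) && flip_for_minus) ss[neg] <- Biostrings::reverseComplement(ss[neg])
    out[ok] <- as.character(ss)
    out
  }
  # upstream exon: splice-proximal end is the right edge on +, left on -
  up_r <- clip_prox(fl$upstream, ifelse(ci$strand == "+", "right", "left"))
  dn_r <- clip_prox(fl$downstream, ifelse(ci$strand == "+", "left", "right"))
  p5 <- ifelse(ci$strand == "+", ci$start, ci$end)
  p3 <- ifelse(ci$strand == "+", ci$end, ci$start)
  list(upstream_exon = getseq(up_r$start, up_r$end),
       intron_5p = extract_window(genome, ci$chrom, p5, ci$strand, c(1L, 50L)),
       intron_3p = extract_window(genome, ci$chrom, p3, ci$strand, c(-50L, -1L)),
       downstream_exon = getseq(dn_r$start, dn_r$end),
       upstream_interval = fl$upstream)
}

# grouped-LDA topic expectations for a list of region sequences
region_topic_features <- function(region_seqs, labels, models = NULL,
                                  n_topics = 6L, group_size = 15L, seed = 1L) {
  fit_models <- is.null(models)
  if (fit_models) models <- list()
  feat <- list()
  for (r in rs_regions) {
    seqs <- region_seqs[[r]]
    ok <- !is.na(seqs) & nchar(seqs) >= 4L
    if (fit_models) {
      sdf <- data.frame(site_type = r, rs_class = labels[ok],
                        intron_position = "any", sequence = seqs[ok],
                        stringsAsFactors = FALSE)
      gm <- grouped_kmer_matrix(sdf, group_size = group_size, k = 4L, seed = seed)
      models[[r]] <- fit_mixture(gm, n_topics = n_topics, seed = seed)
    }
    cnt <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(ifelse(ok, seqs, "AAAA")), width = 4L)
    memb <- topic_expectations(models[[r]], cnt)
    memb[!ok, ] <- NA_real_
    colnames(memb) <- paste0(r, "_topic", seq_len(ncol(memb)))
    feat[[r]] <- memb
  }
  list(features = do.call(cbind, feat), models = models)
}

#' Assemble per-intron feature vectors for RS classification
#'
#' One row per qualifying intron of the scope (gene TPM >= 1; labels come
#' from junction evidence: `RS` for any RS-class junction, `basic` only with
#' exact-junction evidence). Features: grouped-LDA topic expectations of the
#' four regions (upstream exon truncated to 300 nt at the splice-proximal
#' end, intron bases +1..+50 after the 5'SS, -50..-1 before the 3'SS,
#' downstream exon), log10 intron length, log10 gene TPM, and the mean CpG
#' methylation of the upstream exon. For the downstream scope the gene's
#' first-intron topic block and log10 first-intron length are appended.
#' Rows with an undefined region or methylation are dropped and counted.
#'
#' @param classified result of [classify_junctions()].
#' @param annotation a [genome_annotation()].
#' @param genome DNAStringSet.
#' @param tpm TPM table ([read_tpm()] layout).
#' @param methylation methylation records ([read_bedmethyl()] layout).
#' @param scope `"first"` or `"downstream"` introns.
#' @param first_features for `scope = "downstream"`, the `rs_features` object
#'   built for the first introns (its models produce the first-intron block).
#' @param n_topics,group_size,seed topic-model settings.
#' @return object of class `rs_features`: list with `features` (data.frame
#'   incl. `label`), `models` (the four fitted region models), `scope`,
#'   `n_dropped`.
#' @export
build_features <- function(classified, annotation, genome, tpm, methylation,
                           scope = c("first", "downstream"),
                           first_features = NULL, n_topics = 6L,
                           group_size = 15L, seed = 1L) {
  scope <- match.arg(scope)
  ci <- data.table::as.data.table(classified$introns)
  ci[, is_rs := rs_class %in% c("RS5", "RS3", "nested")]
  per <- ci[, .(label = if (any(is_rs)) "RS" else "basic",
                gene_id = gene_id[1L], transcript_id = transcript_id[1L],
                position_class = position_class[1L]),
            by = .(chrom, start, end, strand)]
  per <- if (scope == "first") per[position_class == "first"]
         else per[position_class != "first"]
  if (nrow(per) == 0L) stop("no classified introns in scope '", scope, "'")
  gt <- data.table::as.data.table(gene_tpm(tpm))
  per <- merge(per, gt, by = "gene_id")
  per <- per[TPM >= 1]

  rseq <- region_sequences(per, annotation, genome)
  tf <- region_topic_features(rseq, per$label, n_topics = n_topics,
                              group_size = group_size, seed = seed)

  # upstream-exon methylation
  up <- cbind(per[, .(chrom, strand)], rseq$upstream_interval)
  up <- up[, .(chrom, start, end, strand)]
  up[, row_id := .I]
  em <- exon_methylation(up[!is.na(start)], methylation)
  meth <- rep(NA_real_, nrow(per))
  meth[em$row_id] <- em$mean_percent

  fx <- data.frame(intron_id = paste(per$chrom, per$start, per$end, per$strand, sep = ":"),
                   gene_id = per$gene_id, tf$features,
                   log10_intron_length = log10(per$end - per$start + 1),
                   log10_tpm = log10(per$TPM),
                   upstream_exon_methylation = meth,
                   label = per$label, stringsAsFactors = FALSE)

  if (scope == "downstream") {
    if (is.null(first_features) || !inherits(first_features, "rs_features")) {
      stop("scope 'downstream' needs the first-intron rs_features object")
    }
    intr <- data.table::as.data.table(annotation$introns)
    fi <- intr[position_class == "first"]
    fi <- fi[match(unique(per$gene_id), fi$gene_id)]
    fi <- fi[!is.na(gene_id)]
    fseq <- region_sequences(fi, annotation, genome)
    ftf <- region_topic_features(fseq, labels = NULL, models = first_features$models)
    fmat <- ftf$features
    colnames(fmat) <- paste0("first_", colnames(fmat))
    fdt <- data.frame(gene_id = fi$gene_id, fmat,
                      first_log10_intron_length = log10(fi$end - fi$start + 1),
                      stringsAsFactors = FALSE)
    fx <- merge(fx, fdt, by = "gene_id")
  }

  keep <- stats::complete.cases(fx)
  n_dropped <- sum(!keep)
  fx <- fx[keep, , drop = FALSE]
  structure(list(features = fx, models = tf$models, scope = scope,
                 n_dropped = n_dropped), class = "rs_features")
}

feature_columns <- function(features) {
  setdiff(names(features), c("intron_id", "gene_id", "label"))
}

rf_hyperparameters <- function(scope) {
  # trees / min_samples_split analogue / min leaf size / max depth
  list(num_trees = 100L, min_node_size = 5L,
       max_depth = if (scope == "first") 3L else 2L)
}

#' Train and evaluate a random-forest RS classifier
#'
#' Random forest (100 trees; maximum depth 3 for first introns, 2 for
#' downstream introns; minimum node size 5) with a stratified 1/3 held-out
#' test split. Reports test ROC AUC, ROC and precision-recall points, and
#' impurity feature importances normalized to sum 1. Deterministic given
#' `seed`.
#'
#' @param features an `rs_features` object or its `features` data.frame.
#' @param scope `"first"` or `"downstream"` (sets the depth).
#' @param seed RNG seed for the split and the forest.
#' @param stratified stratify the split by label (default `TRUE`).
#' @param permute_labels permute the labels before splitting (null control).
#' @return object of class `rs_classifier_report`: `auc`, `roc`, `pr`,
#'   `importances`, `model`, `schema`, `hyperparameters`, `seed`, `n_train`,
#'   `n_test`.
#' @export
train_evaluate <- function(features, scope = c("first", "downstream"), seed = 1L,
                           stratified = TRUE, permute_labels = FALSE) {
  scope <- match.arg(scope)
  fx <- if (inherits(features, "rs_features")) features$features else features
  if (!all(c("label") %in% names(fx))) stop("features need a label column")
  classes <- table(fx$label)
  if (length(classes) < 2L) stop("single-class data; cannot train")
  if (min(classes) < 50L) stop("need >= 50 rows per class, got ", min(classes))
  cols <- feature_columns(fx)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  y <- factor(fx$label, levels = c("basic", "RS"))
  if (permute_labels) y <- sample(y)
  n <- length(y)
  test_idx <- if (stratified) {
    unlist(lapply(split(seq_len(n), y), function(ix) {
      sample(ix, max(1L, round(length(ix) / 3)))
    }), use.names = FALSE)
  } else sample.int(n, max(1L, round(n / 3)))
  train_idx <- setdiff(seq_len(n), test_idx)

  hp <- rf_hyperparameters(scope)
  dat <- data.frame(fx[, cols, drop = FALSE], .label = y, check.names = FALSE)
  fit <- ranger::ranger(dependent.variable.name = ".label",
                        data = dat[train_idx, , drop = FALSE],
                        probability = TRUE, num.trees = hp$num_trees,
                        max.depth = hp$max_depth, min.node.size = hp$min_node_size,
                        importance = "impurity", seed = seed, num.threads = 1L)
  prob <- predict(fit, dat[test_idx, , drop = FALSE], num.threads = 1L)$predictions[, "RS"]
  ytest <- y[test_idx]
  roc_obj <- pROC::roc(response = ytest, predictor = prob,
                       levels = c("basic", "RS"), direction = "<", quiet = TRUE)
  roc_df <- data.frame(threshold = roc_obj$thresholds,
                       fpr = 1 - roc_obj$specificities, tpr = roc_obj$sensitivities)
  pr_df <- precision_recall_points(ytest == "RS", prob)
  imp <- fit$variable.importance
  imp <- imp / sum(imp)
  structure(list(auc = as.numeric(roc_obj$auc), roc = roc_df, pr = pr_df,
                 importances = data.frame(feature = names(imp),
                                          importance = unname(imp),
                                          row.names = NULL)[order(-imp), ],
                 model = fit, schema = cols, hyperparameters = hp, seed = seed,
                 scope = scope, n_train = length(train_idx), n_test = length(test_idx)),
            class = "rs_classifier_report")
}

#' @export
print.rs_classifier_report <- function(x, ...) {
  cat(sprintf("rs_classifier_report (%s introns): AUC %.3f (train %d / test %d)\n",
              x$scope, x$auc, x$n_train, x$n_test))
  invisible(x)
}

precision_recall_points <- function(truth, score) {
  ord <- order(-score)
  truth <- truth[ord]
  tp <- cumsum(truth)
  fp <- cumsum(!truth)
  data.frame(threshold = score[ord], precision = tp / (tp + fp),
             recall = tp / sum(truth))
}

#' Covariate-matched subset of RS and basic introns
#'
#' Greedy 1-nearest-neighbour matching without replacement on standardized
#' covariates: each minority-class row is matched to its nearest
#' available majority-class row provided every standardized covariate
#' difference is within `caliper`. Used to ask how well sequence features
#' predict RS once length and expression are balanced away.
#'
#' @param features an `rs_features` object or data.frame with `label`.
#' @param match_on covariate columns (default log length and log TPM).
#' @param caliper maximum standardized per-covariate difference (default 0.2).
#' @param seed order-shuffling seed.
#' @return the matched subset (data.frame, balanced classes) with attribute
#'   `smd` (standardized mean differences after matching).
#' @export
matched_subsets <- function(features, match_on = c("log10_intron_length", "log10_tpm"),
                            caliper = 0.2, seed = 1L) {
  fx <- if (inherits(features, "rs_features")) features$features else features
  if (length(unique(fx$label)) < 2L) stop("both classes must be present")
  z <- scale(as.matrix(fx[, match_on, drop = FALSE]))
  lab <- fx$label
  minority <- names(which.min(table(lab)))
  mi <- which(lab == minority); ma <- which(lab != minority)
  old <- get0(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  mi <- mi[sample.int(length(mi))]
  used <- logical(length(ma))
  pick <- integer(0); keep_mi <- integer(0)
  for (i in mi) {
    dvec <- abs(sweep(z[ma, , drop = FALSE], 2L, z[i, ], "-"))
    okc <- !used & apply(dvec, 1L, max) <= caliper
    if (!any(okc)) next
    dd <- rowSums(dvec^2)
    dd[!okc] <- Inf
    j <- which.min(dd)
    used[j] <- TRUE
    pick <- c(pick, ma[j]); keep_mi <- c(keep_mi, i)
  }
  if (length(pick) == 0L) stop("no matches within caliper")
  out <- fx[c(keep_mi, pick), , drop = FALSE]
  zz <- z[c(keep_mi, pick), , drop = FALSE]
  g <- out$label == minority
  smd <- vapply(seq_along(match_on), function(k) {
    (mean(zz[g, k]) - mean(zz[!g, k])) /
      sqrt((stats::var(zz[g, k]) + stats::var(zz[!g, k])) / 2)
  }, 0)
  names(smd) <- match_on
  attr(out, "smd") <- smd
  out
}

#' Score introns with a trained RS classifier
#'
#' @param features an `rs_features` object or data.frame with the training
#'   schema's columns.
#' @param report a trained [train_evaluate()] report.
#' @return numeric RS probability per row, in `[0, 1]`.
#' @export
score_introns <- function(features, report) {
  stopifnot(inherits(report, "rs_classifier_report"))
  fx <- if (inherits(features, "rs_features")) features$features else features
  miss <- setdiff(report$schema, names(fx))
  if (length(miss) > 0L) stop("feature schema mismatch; missing: ",
                              paste(utils::head(miss, 5L), collapse = ", "))
  predict(report$model, fx[, report$schema, drop = FALSE],
          num.threads = 1L)$predictions[, "RS"]
}
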