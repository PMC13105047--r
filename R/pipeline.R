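# End-to-end orchestration on a synthetic bundle ------------------------------

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  path
}

#' Run the full recursive-splicing pipeline on a synthetic bundle
#'
#' Executes every stage in dependency order — simulate, classify,
#' topics, profiles, methylation, coupling, classifier training, RBNS
#' mapping, validation summary — writing each stage's tables under
#' `out_dir` together with the serialized configuration and a manifest of
#' per-file row counts and md5 checksums. Fully deterministic given the
#' config seed: running twice with the same config yields identical
#' manifests.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [synthetic_config()]; its seed drives every stage.
#' @param scopes classifier scopes to train (default `"first"`).
#' @param min_reads junction read-support threshold (default 3).
#' @param bundle optionally a pre-generated bundle (must match `config`).
#' @return invisibly, a list with the stage results and the `manifest`
#'   data.frame.
#' @export
run_pipeline <- function(out_dir, config = synthetic_config(), scopes = "first",
                         min_reads = 3L, bundle = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  # simulate ------------------------------------------------------------------
  bundle <- stage("simulate", {
    if (is.null(bundle)) generate_rs_bundle(config, dir = file.path(out_dir, "inputs"))
    else bundle
  })
  write_synthetic_config(config, file.path(out_dir, "config.txt"))
  files <- c(files, file.path(out_dir, "config.txt"))

  # classify -------------------------------------------------------------------
  cls <- stage("classify", {
    introns <- extract_constitutive_introns(bundle$annotation)
    classify_junctions(introns, bundle$nascent, bundle$mature,
                       min_unique_reads = min_reads)
  })
  files <- c(files, write_stage(cls$introns, out_dir, "introns_classified.tsv"),
             write_stage(cls$discarded, out_dir, "junctions_discarded.tsv"))

  # topics ----------------------------------------------------------------------
  topics <- stage("topics", {
    ss <- extract_site_sequences(cls, bundle$genome, "canonical5")
    ss <- ss[ss$intron_position == "first", , drop = FALSE]
    attr(ss, "window") <- c(-30L, 50L)
    gm <- grouped_kmer_matrix(ss, group_size = 15L, seed = config$seed)
    fit <- fit_mixture(gm, n_topics = 6L, seed = config$seed)
    list(fit = fit, counts = gm, sequences = ss)
  })
  memb <- data.frame(doc = rownames(topics$fit$memberships), topics$fit$docs,
                     topics$fit$memberships, check.names = FALSE)
  tk <- data.frame(topic = rownames(topics$fit$topics), topics$fit$topics,
                   check.names = FALSE)
  files <- c(files, write_stage(tk, out_dir, "topic_kmer_probs.tsv"),
             write_stage(memb, out_dir, "memberships.tsv"),
             write_stage(driving_kmers(topics$fit), out_dir, "driving_kmers.tsv"))

  # profiles --------------------------------------------------------------------
  profiles <- stage("profiles", {
    ci <- cls$introns[cls$introns$position_class == "first", , drop = FALSE]
    mg <- metagene_gc(ci, bundle$annotation, bundle$genome, bins = 50L)
    wide <- extract_site_sequences(cls, bundle$genome, "canonical5", window = c(-50L, 100L))
    wg <- window_gc(wide[wide$intron_position == "first", , drop = FALSE])
    rs <- topics$sequences$rs_class != "basic"
    te <- tetramer_enrichment(topics$sequences$sequence[rs],
                              topics$sequences$sequence[!rs])
    ic <- pwm_information(topics$sequences)
    list(metagene = mg, window_gc = wg, volcano = te, ic = ic)
  })
  files <- c(files, write_stage(profiles$metagene, out_dir, "metagene_gc.tsv"),
             write_stage(attr(profiles$window_gc, "summary"), out_dir, "window_gc.tsv"),
             write_stage(profiles$volcano, out_dir, "tetramer_volcano.tsv"),
             write_stage(profiles$ic, out_dir, "pwm_ic.tsv"))

  # methylation -----------------------------------------------------------------
  methyl <- stage("methyl", {
    ex <- bundle$annotation$exons
    first_ex <- ex[ex$exon_rank == 1L, , drop = FALSE]
    em <- exon_methylation(first_ex, bundle$methylation)
    ci <- data.table::as.data.table(cls$introns)[position_class == "first"]
    ci[, is_rs := rs_class %in% c("RS5", "RS3", "nested")]
    gene_rs <- ci[, .(rs = any(is_rs)), by = gene_id]
    em$group <- ifelse(em$gene_id %in% gene_rs[rs == TRUE]$gene_id, "RS",
                ifelse(em$gene_id %in% gene_rs$gene_id, "noRS", "undetected"))
    cmp <- compare_methylation_groups(em[em$group != "undetected", , drop = FALSE],
                                      em$group[em$group != "undetected"])
    list(exon_meth = em, tests = cmp$tests, ecdf = cmp$ecdf)
  })
  files <- c(files, write_stage(methyl$exon_meth, out_dir, "exon_methylation.tsv"),
             write_stage(methyl$tests, out_dir, "methylation_tests.tsv"))

  # coupling --------------------------------------------------------------------
  coupling <- stage("coupling", {
    st <- transcript_status(cls)
    ft <- first_downstream_fisher(st)
    list(status = st, fisher = ft)
  })
  ctab <- data.frame(odds_ratio = coupling$fisher$odds_ratio,
                     odds_ratio_cmle = coupling$fisher$odds_ratio_cmle,
                     p_value = coupling$fisher$p_value, n = coupling$fisher$n)
  files <- c(files, write_stage(coupling$status, out_dir, "transcript_status.tsv"),
             write_stage(ctab, out_dir, "coupling_test.tsv"))

  # classifier ------------------------------------------------------------------
  train <- stage("train", {
    out <- list()
    ff <- build_features(cls, bundle$annotation, bundle$genome, bundle$tpm,
                         bundle$methylation, scope = "first", seed = config$seed)
    out$first <- list(features = ff,
                      report = train_evaluate(ff, "first", seed = config$seed))
    if ("downstream" %in% scopes) {
      fd <- build_features(cls, bundle$annotation, bundle$genome, bundle$tpm,
                           bundle$methylation, scope = "downstream",
                           first_features = ff, seed = config$seed)
      out$downstream <- list(features = fd,
                             report = train_evaluate(fd, "downstream", seed = config$seed))
    }
    out
  })
  for (sc in names(train)) {
    rep <- train[[sc]]$report
    files <- c(files,
               write_stage(data.frame(scope = sc, auc = rep$auc,
                                      n_train = rep$n_train, n_test = rep$n_test),
                           out_dir, sprintf("classifier_report_%s.tsv", sc)),
               write_stage(rep$roc, out_dir, sprintf("roc_%s.tsv", sc)),
               write_stage(rep$pr, out_dir, sprintf("pr_%s.tsv", sc)),
               write_stage(rep$importances, out_dir, sprintf("importances_%s.tsv", sc)))
  }
  scores <- data.frame(train$first$features$features[, c("intron_id", "gene_id", "label")],
                       rs_probability = score_introns(train$first$features,
                                                      train$first$report))
  files <- c(files, write_stage(scores, out_dir, "scores_first.tsv"))

  # rbns ------------------------------------------------------------------------
  rbns <- stage("rbns", {
    rm <- load_rbns(bundle$rbns)
    span_win <- c(-75L, 75L + rm$k)
    ss <- do.call(rbind, lapply(c("canonical5", "canonical3", "recursive5", "recursive3"),
                                function(st) extract_site_sequences(cls, bundle$genome,
                                                                    st, window = span_win)))
    attr(ss, "window") <- span_win
    pe <- position_enrichment(ss, rm)
    list(matrix = rm, enrichment = pe, top = rank_proteins(pe))
  })
  files <- c(files, write_stage(rbns$enrichment$E, out_dir, "position_protein_R.tsv"),
             write_stage(rbns$enrichment$log2fc, out_dir, "rbns_log2fc.tsv"),
             write_stage(rbns$top, out_dir, "top_proteins.tsv"))

  # validate: emulate a targeted follow-up of the scored first introns ----------
  validate <- stage("validate", {
    old <- get0(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(config$seed + 7L)
    ti <- data.table::as.data.table(bundle$truth$introns)
    ti[, intron_id := paste(chrom, start, end, strand, sep = ":")]
    v <- data.table::as.data.table(scores)
    v <- merge(v, ti[, .(intron_id, is_rs)], by = "intron_id")
    v[, predicted_rs := rs_probability >= 0.5]
    v[, observed_rs := label == "RS"]
    v[, group := ifelse(observed_rs & predicted_rs, 1L,
                 ifelse(!observed_rs & !predicted_rs, 2L, 3L))]
    v[, rs_read_count := ifelse(is_rs, rnb_pos(.N, 20, 0.5), stats::rbinom(.N, 2L, 0.1))]
    v[, total_reads := rs_read_count + rnb_pos(.N, 40, 0.5)]
    rec <- data.table::setDF(v[, .(intron_id, group, predicted_rs, rs_read_count, total_reads)])
    list(records = rec, rates = group_detection_rates(rec),
         pr = precision_recall_vs_threshold(rec))
  })
  files <- c(files, write_stage(validate$records, out_dir, "validation_records.tsv"),
             write_stage(validate$rates, out_dir, "group_rates.tsv"),
             write_stage(validate$pr, out_dir, "pr_by_threshold.tsv"))

  # manifest --------------------------------------------------------------------
  count_rows <- function(f) max(0L, length(readLines(f)) - 1L)
  manifest <- data.frame(file = basename(files),
                         n_rows = vapply(files, count_rows, 0L),
                         md5 = unname(tools::md5sum(files)), row.names = NULL)
  data.table::fwrite(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t")
  invisible(list(bundle = bundle, classification = cls, topics = topics,
                 profiles = profiles, methylation = methyl, coupling = coupling,
                 training = train, rbns = rbns, validation = validate,
                 manifest = manifest))
}
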