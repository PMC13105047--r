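# First-intron vs downstream-intron RS coupling ------------------------------

#' Per-transcript recursive-splicing status
#'
#' Uses the per-intron evidence from [classify_junctions()]: the first intron
#' is `RS` if it carries any RS-class junction, `noRS` if it has only exact
#' (basic) junction evidence, and `unknown` when no junction was detected.
#' The downstream status is `RS` iff any non-first intron has RS evidence.
#' Transcripts with fewer than `min_introns` detected introns are retained in
#' the table but flagged out of the association test.
#'
#' @param classified result of [classify_junctions()].
#' @param min_introns detected-intron threshold for the Fisher test
#'   (default 3).
#' @return data.frame `transcript_id`, `gene_id`, `n_detected_introns`,
#'   `first_status`, `downstream_status`, `downstream_rs_fraction`,
#'   `in_test_set`.
#' @export
transcript_status <- function(classified, min_introns = 3L) {
  ci <- data.table::as.data.table(classified$introns)
  if (nrow(ci) == 0L) stop("no classified introns")
  ci[, is_rs := rs_class %in% c("RS5", "RS3", "nested")]
  # one detected-intron record per interval (an intron may carry several RS classes)
  per_intron <- ci[, .(is_rs = any(is_rs), gene_id = gene_id[1L],
                       position_class = position_class[1L]),
                   by = .(transcript_id, chrom, start, end, strand)]
  st <- per_intron[, {
    first <- position_class == "first"
    down <- !first
    first_status <- if (!any(first)) "unknown"
                    else if (any(is_rs[first])) "RS" else "noRS"
    list(gene_id = gene_id[1L],
         n_detected_introns = .N,
         first_status = first_status,
         downstream_status = if (any(is_rs[down])) "RS" else "noRS",
         downstream_rs_fraction = if (any(down)) mean(is_rs[down]) else 0)
  }, by = transcript_id]
  st[, in_test_set := n_detected_introns >= min_introns & first_status != "unknown"]
  data.table::setDF(st)
}

#' Fisher's exact association between first-intron and downstream RS
#'
#' Builds the 2x2 table of `first_status` (RS/noRS) by `downstream_status`
#' over transcripts in the test set and reports the sample (cross-product)
#' odds ratio with a Haldane 0.5 correction when any cell is zero, and the
#' two-sided Fisher's exact p-value. The conditional-MLE odds ratio from
#' [stats::fisher.test()] is returned alongside.
#'
#' @param statuses data.frame from [transcript_status()].
#' @return list `table` (2x2), `odds_ratio` (cross-product),
#'   `odds_ratio_cmle`, `p_value`, `haldane_corrected`, `n`.
#' @export
first_downstream_fisher <- function(statuses) {
  st <- statuses[statuses$in_test_set, , drop = FALSE]
  if (nrow(st) == 0L) stop("no transcripts eligible for the association test")
  tab <- table(factor(st$first_status, levels = c("RS", "noRS")),
               factor(st$downstream_status, levels = c("RS", "noRS")))
  haldane <- any(tab == 0L)
  tc <- tab + if (haldane) 0.5 else 0
  or <- (tc[1L, 1L] * tc[2L, 2L]) / (tc[1L, 2L] * tc[2L, 1L])
  ft <- stats::fisher.test(tab)
  list(table = tab, odds_ratio = unname(or),
       odds_ratio_cmle = unname(ft$estimate), p_value = ft$p.value,
       haldane_corrected = haldane, n = sum(tab))
}

#' Six-type transcript classification
#'
#' Cross-classifies `first_status` (RS / noRS / unknown) with
#' `downstream_status` (RS / noRS) into the six splice-status transcript
#' types and counts them.
#'
#' @param statuses data.frame from [transcript_status()].
#' @return data.frame `first_status`, `downstream_status`, `n`.
#' @export
transcript_types <- function(statuses) {
  tab <- table(factor(statuses$first_status, levels = c("RS", "noRS", "unknown")),
               factor(statuses$downstream_status, levels = c("RS", "noRS")))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("first_status", "downstream_status", "n")
  out
}
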