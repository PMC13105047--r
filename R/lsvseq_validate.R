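# Targeted-validation (LSV-seq) summary arithmetic ---------------------------

#' Per-group recursive-splicing detection rates
#'
#' A target intron counts as detected when its recursive-junction read count
#' reaches `min_reads` (default 1: any potential recursive junction counts).
#' Percentages are rounded to two decimals; empty groups report NA.
#'
#' @param records data.frame with `intron_id`, `group`, `predicted_rs`,
#'   `rs_read_count` (and optionally `total_reads`).
#' @param min_reads detection read threshold (default 1; the stricter
#'   published filters >2 and >=10 are available via this argument).
#' @return data.frame `group`, `tested`, `detected`, `percent`.
#' @export
group_detection_rates <- function(records, min_reads = 1L) {
  dt <- data.table::as.data.table(records)
  if (!all(c("group", "rs_read_count") %in% names(dt))) {
    stop("records need columns group and rs_read_count")
  }
  lev <- sort(unique(dt$group))
  out <- dt[, .(tested = .N, detected = sum(rs_read_count >= min_reads)), by = group]
  out[, percent := round(100 * detected / tested, 2)]
  out <- out[match(lev, group)]
  res <- data.table::setDF(out)
  res$percent[res$tested == 0L] <- NA_real_
  res
}

#' Precision and recall of LSV-seq detection across read thresholds
#'
#' Follows the published convention: the classifier prediction
#' (`predicted_rs`) is treated as truth, and the LSV-seq observation at read
#' threshold `t` (`rs_read_count >= t`) as the call. Precision is
#' TP/(TP+FP), recall TP/(TP+FN); a threshold yielding zero observed
#' positives reports NA precision.
#'
#' @param records data.frame with `predicted_rs` (logical) and
#'   `rs_read_count`.
#' @param thresholds integer vector of read thresholds.
#' @return data.frame `threshold`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `recall`.
#' @export
precision_recall_vs_threshold <- function(records, thresholds = c(1L, 3L, 5L, 10L)) {
  dt <- data.table::as.data.table(records)
  if (!all(c("predicted_rs", "rs_read_count") %in% names(dt))) {
    stop("records need columns predicted_rs and rs_read_count")
  }
  if (anyNA(dt$predicted_rs)) stop("predicted_rs must be defined for all records")
  rows <- lapply(thresholds, function(t) {
    obs <- dt$rs_read_count >= t
    tp <- sum(obs & dt$predicted_rs)
    fp <- sum(obs & !dt$predicted_rs)
    fn <- sum(!obs & dt$predicted_rs)
    tn <- sum(!obs & !dt$predicted_rs)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
               recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn))
  })
  do.call(rbind, rows)
}
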