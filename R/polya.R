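# Poly(A) tail-length QC filtering, summaries and distributions.

#' Keep poly(A) records passing QC
#'
#' Default policy keeps only `qc_tag == "PASS"` (other nanopolish tags flag
#' adapter/segmentation problems); removal counts per tag are logged and
#' attached as attribute `removed_by_tag`.
#'
#' @param records poly(A) record table from [read_polya()].
#' @param accepted_tags character vector of tags to keep.
#' @return Filtered record table.
#' @export
filter_polya_pass <- function(records, accepted_tags = "PASS") {
  dt <- data.table::as.data.table(records)
  if (!nrow(dt)) return(dt[])
  keep <- dt$qc_tag %in% accepted_tags
  removed <- table(dt$qc_tag[!keep])
  if (length(removed)) {
    ed_log("filter_polya_pass: removed %d record(s): %s", sum(removed),
           paste(sprintf("%s=%d", names(removed), removed), collapse = ", "))
  }
  out <- dt[keep]
  data.table::setattr(out, "removed_by_tag", removed)
  out[]
}

#' Per-transcript and per-condition poly(A) length summaries
#'
#' Per (transcript, condition): read count, mean and median tail length.
#' Per condition, two grand means are emitted: over reads and over
#' per-transcript means (the published mean could be either; both are
#' reported).
#'
#' @param records filtered poly(A) records with a `sample_id` column.
#' @param condition_map named sample-to-condition vector.
#' @return List with `per_transcript` and `per_condition` data.tables.
#' @export
polya_summaries <- function(records, condition_map) {
  dt <- data.table::as.data.table(records)
  condition_map <- validate_condition_map(condition_map, unique(dt$sample_id))
  dt[, condition := unname(condition_map[sample_id])]
  per_tx <- dt[, .(n_reads = .N,
                   mean_length = mean(polya_length),
                   median_length = median(polya_length)),
               by = .(transcript_id, condition)]
  data.table::setkey(per_tx, transcript_id, condition)
  per_cond <- dt[, .(n_reads = .N, mean_read_level = mean(polya_length),
                     median_read_level = median(polya_length)),
                 by = condition]
  tx_level <- per_tx[, .(mean_transcript_level = mean(mean_length)), by = condition]
  per_cond <- merge(per_cond, tx_level, by = "condition")
  list(per_transcript = per_tx[], per_condition = per_cond[])
}

#' Binned poly(A) length distribution per condition
#'
#' Fixed-width bins over `range`, plus one overflow bin for tails longer
#' than the range; bin counts conserve the total record number.
#'
#' @param records poly(A) records; a `condition` column is used if present,
#'   else supply `condition_map` to derive it from `sample_id`, else all
#'   records form one group.
#' @param bin_width bin width in nt (default 10).
#' @param range histogram range in nt (default `c(0, 400)`).
#' @param condition_map optional named sample-to-condition vector.
#' @return `data.table` (`bin_left`, `bin_right`, `count`, `condition`);
#'   the overflow bin has `bin_right = Inf`.
#' @export
polya_histogram <- function(records, bin_width = 10, range = c(0, 400),
                            condition_map = NULL) {
  dt <- data.table::as.data.table(records)
  if (any(dt$polya_length < 0)) stopf("polya_histogram: negative poly(A) length")
  if (!"condition" %in% names(dt)) {
    if (!is.null(condition_map)) {
      dt[, condition := unname(condition_map[sample_id])]
    } else {
      dt[, condition := "all"]
    }
  }
  breaks <- seq(range[1], range[2], by = bin_width)
  out <- dt[, {
    idx <- findInterval(polya_length, breaks)   # 0 never occurs (length >= 0)
    over <- sum(idx >= length(breaks))
    cnt <- tabulate(idx[idx < length(breaks)], nbins = length(breaks) - 1L)
    .(bin_left = c(breaks[-length(breaks)], range[2]),
      bin_right = c(breaks[-1], Inf),
      count = c(cnt, over))
  }, by = condition]
  data.table::setcolorder(out, c("bin_left", "bin_right", "count", "condition"))
  out[]
}
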