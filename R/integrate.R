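# CPM normalisation, expression filtering, the cross-omics Pearson
# correlation suite, and the multi-omics significant-set overlap.

#' Counts-per-million normalisation
#'
#' `cell / column_total * 1e6`; every output column sums to one million.
#'
#' @param counts raw count matrix (see [abundance_matrix()]).
#' @return Matrix with `kind = "cpm"`.
#' @export
cpm_normalize <- function(counts) {
  m <- abundance_matrix(unclass_matrix(counts), "counts")
  totals <- colSums(m)
  if (any(totals == 0)) {
    stopf("cpm_normalize: zero library size for sample %s",
          colnames(m)[which(totals == 0)[1]])
  }
  out <- sweep(m, 2L, totals, "/") * 1e6
  abundance_matrix(out, "cpm")
}

unclass_matrix <- function(m) {
  attr(m, "kind") <- NULL
  m
}

#' Expression filter on a CPM matrix
#'
#' Keeps rows with at least `min_samples` cells at or above `min_cpm`
#' (boundary inclusive).
#'
#' @param cpm_matrix CPM matrix from [cpm_normalize()].
#' @param min_cpm CPM threshold (default 2).
#' @param min_samples number of qualifying samples required (default 2).
#' @return Filtered CPM matrix.
#' @export
expression_filter <- function(cpm_matrix, min_cpm = 2, min_samples = 2L) {
  if (!identical(attr(cpm_matrix, "kind"), "cpm")) {
    stopf("expression_filter: input must be a CPM matrix")
  }
  keep <- rowSums(cpm_matrix >= min_cpm) >= min_samples
  ed_log("expression_filter: kept %d of %d rows (>= %g cpm in >= %d samples)",
         sum(keep), length(keep), min_cpm, min_samples)
  out <- cpm_matrix[keep, , drop = FALSE]
  attr(out, "kind") <- "cpm"
  out
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment r with the t transform `t = r * sqrt((n-2)/(1-r^2))` on
#' `n - 2` degrees of freedom. Incomplete pairs (NA/NaN in either vector)
#' are removed pairwise-complete and the adjusted n is reported.
#'
#' @param x,y numeric vectors of equal length.
#' @param pair,condition labels copied into the result row.
#' @return One-row `data.frame` (`pair`, `condition`, `r`, `p_value`, `n`).
#' @export
pearson_with_p <- function(x, y, pair = "x~y", condition = "all") {
  if (length(x) != length(y)) stopf("pearson_with_p: length mismatch")
  ok <- is.finite(x) & is.finite(y)
  if (any(!ok)) {
    ed_log("pearson_with_p [%s]: dropped %d incomplete pair(s)", pair, sum(!ok))
    x <- x[ok]; y <- y[ok]
  }
  n <- length(x)
  if (n < 3L) stopf("pearson_with_p: need at least 3 complete pairs, got %d", n)
  if (sd(x) == 0 || sd(y) == 0) stopf("pearson_with_p: constant vector")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  data.frame(pair = pair, condition = condition, r = r, p_value = p, n = n)
}

layer_dt <- function(layer, value_name) {
  dt <- data.table::as.data.table(layer)
  assert_cols(dt, c("transcript_id", "condition", "value"), value_name)
  dt[, .(transcript_id = as.character(transcript_id),
         condition = as.character(condition), value = as.numeric(value))]
}

#' Cross-omics Pearson correlation suite
#'
#' Computes, per condition, the six variable pairs examined along the
#' pipeline: global modification ratio vs transcript abundance, m6A ratio vs
#' abundance, poly(A) length vs m6A ratio, poly(A) length vs abundance, m6A
#' ratio vs protein abundance, and poly(A) length vs protein abundance.
#' Layers are intersected on transcript ids; protein values are mapped to
#' transcripts through `id_map`. Abundance and protein values are expected on
#' the log scale (see [run_pipeline()], which feeds `log2(CPM + 1)` and
#' log2 protein means).
#'
#' @param mod_ratio,m6a_ratio,abundance,polya data.frames with columns
#'   `transcript_id`, `condition`, `value`; any may be `NULL` to skip its
#'   pairs.
#' @param protein data.frame (`protein_id`, `condition`, `value`) or `NULL`.
#' @param id_map transcript-to-protein map (needed when `protein` is given).
#' @return `data.table` of [pearson_with_p()] rows; pairs with fewer than 3
#'   common features are skipped with a warning.
#' @export
correlation_suite <- function(mod_ratio = NULL, m6a_ratio = NULL,
                              abundance = NULL, polya = NULL,
                              protein = NULL, id_map = NULL) {
  layers <- list()
  if (!is.null(mod_ratio)) layers$mod_ratio <- layer_dt(mod_ratio, "mod_ratio")
  if (!is.null(m6a_ratio)) layers$m6a_ratio <- layer_dt(m6a_ratio, "m6a_ratio")
  if (!is.null(abundance)) layers$abundance <- layer_dt(abundance, "abundance")
  if (!is.null(polya)) layers$polya <- layer_dt(polya, "polya")
  if (!is.null(protein)) {
    pdt <- data.table::as.data.table(protein)
    assert_cols(pdt, c("protein_id", "condition", "value"), "protein")
    if (is.null(id_map)) stopf("correlation_suite: protein layer needs id_map")
    map <- data.table::as.data.table(id_map)
    pdt <- merge(pdt, map, by = "protein_id")
    layers$protein <- pdt[, .(transcript_id = as.character(transcript_id),
                              condition = as.character(condition),
                              value = as.numeric(value))]
  }
  pairs <- list(
    c("mod_ratio", "abundance"),
    c("m6a_ratio", "abundance"),
    c("polya", "m6a_ratio"),
    c("polya", "abundance"),
    c("m6a_ratio", "protein"),
    c("polya", "protein"))
  conds <- sort(unique(unlist(lapply(layers, function(l) unique(l$condition)))))
  rows <- list()
  for (pr in pairs) {
    if (is.null(layers[[pr[1]]]) || is.null(layers[[pr[2]]])) next
    for (cn in conds) {
      a <- layers[[pr[1]]][condition == cn]
      b <- layers[[pr[2]]][condition == cn]
      j <- merge(a, b, by = "transcript_id", suffixes = c(".a", ".b"))
      lbl <- paste(pr, collapse = "~")
      if (nrow(j) < 3L) {
        warning(sprintf("correlation_suite: skipped %s [%s], only %d common feature(s)",
                        lbl, cn, nrow(j)), call. = FALSE)
        next
      }
      rows[[length(rows) + 1L]] <-
        pearson_with_p(j$value.a, j$value.b, pair = lbl, condition = cn)
    }
  }
  data.table::rbindlist(rows)
}

#' Overlap of significant feature sets from three omics approaches
#'
#' Exclusive pairwise intersections, the triple intersection, and the total
#' number of features significant in at least two approaches.
#'
#' @param set_de,set_mod,set_prot character vectors of feature ids
#'   significant in, respectively, differential expression, differential
#'   modification, and differential proteomics (shared id namespace).
#' @return List of class `overlap_report` with single-set sizes, exclusive
#'   single/pair counts, `all_three`, and `total_ge2`.
#' @export
multiomics_overlap <- function(set_de, set_mod, set_prot) {
  A <- unique(as.character(set_de))
  B <- unique(as.character(set_mod))
  C <- unique(as.character(set_prot))
  abc <- intersect(intersect(A, B), C)
  ab <- setdiff(intersect(A, B), C)
  ac <- setdiff(intersect(A, C), B)
  bc <- setdiff(intersect(B, C), A)
  out <- list(
    n_de = length(A), n_mod = length(B), n_prot = length(C),
    de_only = length(setdiff(A, union(B, C))),
    mod_only = length(setdiff(B, union(A, C))),
    prot_only = length(setdiff(C, union(A, B))),
    de_mod = length(ab), de_prot = length(ac), mod_prot = length(bc),
    all_three = length(abc),
    total_ge2 = length(ab) + length(ac) + length(bc) + length(abc))
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Significant-set overlap\n")
  cat(sprintf("  sets: DE=%d, modification=%d, proteomics=%d\n",
              x$n_de, x$n_mod, x$n_prot))
  cat(sprintf("  pairwise (exclusive): DE&mod=%d, DE&prot=%d, mod&prot=%d\n",
              x$de_mod, x$de_prot, x$mod_prot))
  cat(sprintf("  all three: %d; significant in >=2 approaches: %d\n",
              x$all_three, x$total_ge2))
  invisible(x)
}
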