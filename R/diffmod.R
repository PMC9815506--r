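# Per-position differential modification calling between two conditions.
#
# Replicates of a condition are pooled into a single 2x2 table per position
# (modified / unmodified x control / treatment), tested with a two-sided
# Fisher exact test, and effect size is a Haldane-pseudocounted log2 ratio of
# modified fractions. Positions pass only if both pooled coverages reach the
# minimum depth, which keeps one-sided tables out of the test.

#' Pool replicate counts into per-condition totals per position
#'
#' @param x a [modcall_table()].
#' @param reference condition label to treat as the reference (denominator of
#'   the fold change). Defaults to `"control"` when present, else the
#'   alphabetically first label.
#' @return `data.table` of class `pooled_positions` with per-position pooled
#'   coverage (`N_c`, `N_t`) and modified counts (`m_c`, `m_t`); positions
#'   absent from one condition get zero on that side. Attributes `reference`
#'   and `treatment` carry the labels.
#' @export
pool_counts <- function(x, reference = NULL) {
  cm <- condition_map(x)
  if (is.null(cm)) stopf("pool_counts: input has no condition_map")
  conds <- sort(unique(unname(cm)))
  if (is.null(reference)) reference <- if ("control" %in% conds) "control" else conds[1]
  if (!reference %in% conds) stopf("pool_counts: unknown reference condition %s", reference)
  treatment <- setdiff(conds, reference)
  dt <- data.table::as.data.table(x)
  dt[, cond := unname(cm[sample_id])]
  agg <- dt[, .(N = sum(coverage), m = sum(modified_count)),
            by = .(transcript_id, position, ref_base, cond)]
  wide <- data.table::dcast(agg, transcript_id + position + ref_base ~ cond,
                            value.var = c("N", "m"), fill = 0L)
  for (nm in c(paste0("N_", c(reference, treatment)), paste0("m_", c(reference, treatment)))) {
    if (!nm %in% names(wide)) wide[, (nm) := 0L]
  }
  data.table::setnames(wide,
                       c(paste0("N_", reference), paste0("m_", reference),
                         paste0("N_", treatment), paste0("m_", treatment)),
                       c("N_c", "m_c", "N_t", "m_t"))
  data.table::setcolorder(wide, c("transcript_id", "position", "ref_base",
                                  "m_c", "N_c", "m_t", "N_t"))
  data.table::setkey(wide, transcript_id, position)
  data.table::setattr(wide, "reference", reference)
  data.table::setattr(wide, "treatment", treatment)
  data.table::setattr(wide, "class", c("pooled_positions", class(data.table::data.table())))
  wide[]
}

#' Minimum-depth filter on pooled positions
#'
#' Retains positions with at least `min_cov` pooled reads in *each*
#' condition (boundary inclusive). The count of removed positions is logged
#' and attached as attribute `removed`.
#'
#' @param pooled output of [pool_counts()].
#' @param min_cov minimum pooled reads per condition (default 50).
#' @return Filtered `pooled_positions`.
#' @export
coverage_filter <- function(pooled, min_cov = 50L) {
  if (min_cov < 1L) stopf("coverage_filter: min_cov must be >= 1")
  keep <- pooled$N_c >= min_cov & pooled$N_t >= min_cov
  out <- pooled[keep]
  removed <- sum(!keep)
  ed_log("coverage_filter: removed %d of %d positions below %d reads/condition",
         removed, nrow(pooled), min_cov)
  for (a in c("reference", "treatment")) {
    data.table::setattr(out, a, attr(pooled, a, exact = TRUE))
  }
  data.table::setattr(out, "removed", removed)
  data.table::setattr(out, "class", class(pooled))
  out[]
}

#' Two-sided Fisher exact test for a 2x2 modification table
#'
#' Conditions on all margins and sums hypergeometric probabilities no larger
#' than that of the observed table (probability-mass ordering); tables whose
#' probability ties the observed one within relative tolerance `rel_tol` are
#' included in the sum. Vectorised over tables.
#'
#' @param m_c,u_c modified / unmodified pooled reads, reference condition.
#' @param m_t,u_t modified / unmodified pooled reads, treatment condition.
#' @param rel_tol relative tie tolerance on the probability-mass ordering.
#' @return p-values in (0, 1].
#' @export
fisher_exact_2x2 <- function(m_c, u_c, m_t, u_t, rel_tol = 1e-7) {
  n <- max(length(m_c), length(u_c), length(m_t), length(u_t))
  m_c <- rep_len(as.numeric(m_c), n); u_c <- rep_len(as.numeric(u_c), n)
  m_t <- rep_len(as.numeric(m_t), n); u_t <- rep_len(as.numeric(u_t), n)
  if (any(c(m_c, u_c, m_t, u_t) < 0)) stopf("fisher_exact_2x2: negative input")
  N1 <- m_c + u_c; N2 <- m_t + u_t; K <- m_c + m_t
  if (any(N1 + N2 == 0)) stopf("fisher_exact_2x2: all margins zero")
  vapply(seq_len(n), function(i) {
    lo <- max(0, K[i] - N2[i]); hi <- min(K[i], N1[i])
    if (lo == hi) return(1)
    k <- lo:hi
    probs <- dhyper(k, N1[i], N2[i], K[i])
    p_obs <- probs[k == m_c[i]]
    min(1, sum(probs[probs <= p_obs * (1 + rel_tol)]))
  }, numeric(1))
}

#' Pseudocounted log2 fold change of modified fractions
#'
#' `f = (m + pseudocount) / (N + 2 * pseudocount)` per condition;
#' returns `log2(f_t / f_c)` (treatment over reference). The Haldane-style
#' pseudocount keeps the ratio finite at 0% or 100% modification; the value
#' is antisymmetric under swapping the two conditions.
#'
#' @param m_c,N_c modified count and pooled coverage, reference condition.
#' @param m_t,N_t modified count and pooled coverage, treatment condition.
#' @param pseudocount additive constant (default 0.5; depth gets twice it).
#' @return Numeric log2 fold changes.
#' @export
log2fc_mod <- function(m_c, N_c, m_t, N_t, pseudocount = 0.5) {
  if (any(N_c < 0 | N_t < 0)) stopf("log2fc_mod: negative coverage")
  if (any(N_c == 0 & N_t == 0)) stopf("log2fc_mod: both coverages zero")
  f_c <- (m_c + pseudocount) / (N_c + 2 * pseudocount)
  f_t <- (m_t + pseudocount) / (N_t + 2 * pseudocount)
  log2(f_t / f_c)
}

#' Per-position differential modification scan
#'
#' The full caller: pool replicates, apply the per-condition depth filter,
#' Fisher-test every retained position, compute the pseudocounted log2 fold
#' change, and classify positions as `over` (p below `alpha` and log2fc above
#' `+lfc_min`), `under` (p below `alpha` and log2fc below `-lfc_min`) or
#' `ns`. With `adjust = "BH"` the Benjamini-Hochberg q-value replaces the raw
#' p in the significance gate (q-values are always reported alongside).
#'
#' @param x a [modcall_table()].
#' @param min_cov pooled per-condition depth threshold (default 50).
#' @param alpha significance level (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 0.5).
#' @param adjust `"none"` (raw p, the default) or `"BH"`.
#' @param reference reference condition label (see [pool_counts()]).
#' @param pseudocount passed to [log2fc_mod()].
#' @return `data.table` with columns `transcript_id, position, ref_base, m_c,
#'   N_c, m_t, N_t, f_c, f_t, log2fc, p_value, q_value, status`, ordered by
#'   transcript and position. Attribute `tally` summarises per-transcript
#'   over/under counts; attribute `removed` carries the depth-filter loss.
#' @export
diffmod_scan <- function(x, min_cov = 50L, alpha = 0.05, lfc_min = 0.5,
                         adjust = c("none", "BH"), reference = NULL,
                         pseudocount = 0.5) {
  adjust <- match.arg(adjust)
  pooled <- pool_counts(x, reference = reference)
  if (!nrow(pooled)) stopf("diffmod_scan: empty modification table")
  filt <- coverage_filter(pooled, min_cov = min_cov)
  res <- data.table::as.data.table(filt)
  if (nrow(res)) {
    res[, `:=`(
      f_c = (m_c + pseudocount) / (N_c + 2 * pseudocount),
      f_t = (m_t + pseudocount) / (N_t + 2 * pseudocount),
      log2fc = log2fc_mod(m_c, N_c, m_t, N_t, pseudocount = pseudocount),
      p_value = fisher_exact_2x2(m_c, N_c - m_c, m_t, N_t - m_t))]
    res[, q_value := p.adjust(p_value, method = "BH")]
    gate <- if (adjust == "BH") res$q_value else res$p_value
    res[, status := data.table::fifelse(
      gate < alpha & log2fc > lfc_min, "over",
      data.table::fifelse(gate < alpha & log2fc < -lfc_min, "under", "ns"))]
  } else {
    res[, `:=`(f_c = numeric(), f_t = numeric(), log2fc = numeric(),
               p_value = numeric(), q_value = numeric(), status = character())]
  }
  data.table::setkey(res, transcript_id, position)
  per_tx <- res[, .(n_over = sum(status == "over"),
                    n_under = sum(status == "under")), by = transcript_id]
  tally <- list(
    n_positions_tested = nrow(res),
    n_over_positions = sum(res$status == "over"),
    n_under_positions = sum(res$status == "under"),
    n_sig_positions = sum(res$status != "ns"),
    n_transcripts_over = sum(per_tx$n_over > 0L),
    n_transcripts_under = sum(per_tx$n_under > 0L),
    n_transcripts_both = sum(per_tx$n_over > 0L & per_tx$n_under > 0L),
    n_transcripts_modified = sum(per_tx$n_over + per_tx$n_under > 0L),
    per_transcript = per_tx)
  data.table::setattr(res, "tally", tally)
  data.table::setattr(res, "removed", attr(filt, "removed", exact = TRUE))
  data.table::setattr(res, "thresholds",
                      list(min_cov = min_cov, alpha = alpha, lfc_min = lfc_min,
                           adjust = adjust, pseudocount = pseudocount))
  data.table::setattr(res, "reference", attr(filt, "reference", exact = TRUE))
  data.table::setattr(res, "treatment", attr(filt, "treatment", exact = TRUE))
  res[]
}

#' Base composition of modified positions
#'
#' Percentage of positions per reference nucleobase (A/C/G/U), optionally
#' split by a `condition` column; percentages sum to 100 within each group.
#'
#' @param positions data.frame with `ref_base` (or `transcript_id`/`position`
#'   plus `sequences` for lookup) and optionally `condition`.
#' @param sequences optional named RNA sequences for ref_base lookup.
#' @return `data.table` (`condition`, `base`, `percent`).
#' @export
base_composition <- function(positions, sequences = NULL) {
  dt <- data.table::as.data.table(positions)
  if (!nrow(dt)) stopf("base_composition: empty input")
  if (!"ref_base" %in% names(dt) || anyNA(dt$ref_base)) {
    if (is.null(sequences)) stopf("base_composition: ref_base unknown and no sequences given")
    dt <- set_ref_base(dt, sequences)
  }
  if (!"condition" %in% names(dt)) dt[, condition := "all"]
  grid <- data.table::CJ(condition = unique(dt$condition), base = RNA_BASES)
  counts <- dt[, .N, by = .(condition, base = ref_base)]
  out <- merge(grid, counts, by = c("condition", "base"), all.x = TRUE)
  out[is.na(N), N := 0L]
  out[, percent := 100 * N / sum(N), by = condition]
  out[, N := NULL]
  out[]
}

#' Per-transcript pooled modification ratio
#'
#' `sum(m) / sum(N)` over a transcript's retained positions for one
#' condition; transcripts with zero pooled coverage are omitted (logged).
#'
#' @param pooled output of [pool_counts()] or [coverage_filter()].
#' @param condition `"reference"` or `"treatment"` side.
#' @return `data.table` (`transcript_id`, `mod_ratio`, `n_positions`,
#'   `condition` label).
#' @export
transcript_mod_ratio <- function(pooled, condition = c("reference", "treatment")) {
  condition <- match.arg(condition)
  dt <- data.table::as.data.table(pooled)
  if (condition == "reference") {
    agg <- dt[, .(m = sum(m_c), N = sum(N_c), n_positions = .N), by = transcript_id]
    label <- attr(pooled, "reference", exact = TRUE) %||% "reference"
  } else {
    agg <- dt[, .(m = sum(m_t), N = sum(N_t), n_positions = .N), by = transcript_id]
    label <- attr(pooled, "treatment", exact = TRUE) %||% "treatment"
  }
  dropped <- agg[N == 0L]
  if (nrow(dropped)) {
    ed_log("transcript_mod_ratio: omitted %d transcript(s) with no retained coverage",
           nrow(dropped))
  }
  out <- agg[N > 0L, .(transcript_id, mod_ratio = m / N, n_positions,
                       condition = label)]
  data.table::setkey(out, transcript_id)
  out[]
}

#' Arithmetic consistency of a printed count split
#'
#' The report-level tally check: do the parts of a published split sum to the
#' published total?
#'
#' @param parts integer vector of subset counts.
#' @param total published total.
#' @return List with `parts_sum`, `total` and logical `consistent`.
#' @export
check_count_split <- function(parts, total) {
  s <- sum(parts)
  list(parts_sum = s, total = total, consistent = isTRUE(all.equal(s, total)))
}
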