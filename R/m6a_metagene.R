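# RRACH m6A site scanning, kmer frequencies and metagene density profiles.

#' The twelve concrete RRACH 5-mers
#'
#' R in {A,G}, central methylated A, then C, then H in {A,U,C}.
#'
#' @return Character vector of the 12 kmers, sorted.
#' @export
rrach_kmers <- function() {
  g <- expand.grid(r1 = c("A", "G"), r2 = c("A", "G"), a = "A", c = "C",
                   h = c("A", "C", "U"), stringsAsFactors = FALSE)
  sort(apply(g, 1L, paste0, collapse = ""))
}

#' Scan transcript sequences for RRACH m6A consensus sites
#'
#' Reports one site per position whose centred 5-mer matches RRACH
#' (overlapping matches included); the first and last two positions of a
#' transcript can never host a site because the 5-mer must fit.
#'
#' @param sequences named character vector / `RNAStringSet`, or a single
#'   unnamed sequence combined with `transcript_id`.
#' @param transcript_id id used when `sequences` is a single bare string.
#' @return `data.table` (`transcript_id`, `position` 0-based offset of the
#'   methylated A, `kmer`).
#' @export
find_rrach_sites <- function(sequences, transcript_id = NULL) {
  seqs <- as_rna_character(sequences)
  if (!is.null(transcript_id) && length(seqs) == 1L) names(seqs) <- transcript_id
  bad <- regexpr("[^ACGU]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stopf("find_rrach_sites: non-alphabet character in %s at offset %d",
          names(seqs)[i], as.integer(bad[i]) - 1L)
  }
  ss <- Biostrings::RNAStringSet(seqs)
  hits <- Biostrings::vmatchPattern("RRACH", ss, fixed = FALSE)
  out <- data.table::rbindlist(lapply(seq_along(hits), function(i) {
    st <- BiocGenerics::start(hits[[i]])
    if (!length(st)) return(NULL)
    data.table::data.table(transcript_id = names(seqs)[i],
                           position = st + 1L,   # 1-based start + 2 - 1 -> 0-based A
                           kmer = substring(seqs[i], st, st + 4L))
  }))
  if (!nrow(out)) {
    out <- data.table::data.table(transcript_id = character(),
                                  position = integer(), kmer = character())
  }
  data.table::setkey(out, transcript_id, position)
  out[]
}

#' Kmer frequency table over the 12 RRACH variants
#'
#' @param sites `data.table` from [find_rrach_sites()] (needs a `kmer`
#'   column).
#' @return `data.table` (`kmer`, `count`, `frequency`) with all 12 variants
#'   present (zeros included); frequencies sum to 1. Empty input returns an
#'   all-zero table flagged with attribute `degenerate = TRUE`.
#' @export
kmer_frequencies <- function(sites) {
  kmers <- rrach_kmers()
  dt <- data.table::as.data.table(sites)
  if (nrow(dt)) {
    bad <- setdiff(unique(dt$kmer), kmers)
    if (length(bad)) stopf("kmer_frequencies: non-RRACH kmer in input: %s", bad[1])
  }
  counts <- if (nrow(dt)) dt[, .N, by = .(kmer)] else
    data.table::data.table(kmer = character(), N = integer())
  out <- merge(data.table::data.table(kmer = kmers), counts, by = "kmer", all.x = TRUE)
  out[is.na(N), N := 0L]
  data.table::setnames(out, "N", "count")
  total <- sum(out$count)
  out[, frequency := if (total > 0L) count / total else 0]
  data.table::setattr(out, "degenerate", total == 0L)
  out[]
}

site_conditions <- function(dt) {
  if (!"condition" %in% names(dt)) dt[, condition := "all"]
  dt
}

make_profile <- function(coord_dt, breaks, axis) {
  # coord_dt: data.table(coord, condition); unit-area histogram per condition
  width <- diff(breaks)
  prof <- coord_dt[, {
    idx <- findInterval(coord, breaks, rightmost.closed = TRUE)
    cnt <- tabulate(idx, nbins = length(breaks) - 1L)
    .(bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
      count = cnt, density = cnt / (sum(cnt) * width))
  }, by = condition]
  data.table::setcolorder(prof, c("bin_left", "bin_right", "count", "density",
                                  "condition"))
  data.table::setattr(prof, "axis", axis)
  prof[]
}

#' Metagene axis coordinates for sites
#'
#' Maps each site to its relative metagene coordinate. On the `"full"` axis
#' this is `position / (length - 1)` in `[0, 1]`; on the `"regions"` axis it
#' is `r + (position - region_start) / region_length` in `[0, 3)` with
#' `r = 0, 1, 2` indexing 5'UTR, CDS, 3'UTR (region membership
#' start-inclusive, end-exclusive).
#'
#' @param sites site table with `transcript_id`, `position` and optionally
#'   `condition`.
#' @param annotations annotation table (`transcript_id`, `length`, and for
#'   the region axis `cds_start`, `cds_end`).
#' @param axis `"full"` or `"regions"`.
#' @return Site table with `coord` (and `region` on the region axis) added;
#'   sites on length-1 transcripts are dropped with a warning on the full
#'   axis.
#' @export
metagene_coords <- function(sites, annotations, axis = c("full", "regions")) {
  axis <- match.arg(axis)
  ann <- data.table::as.data.table(annotations)
  dt <- site_conditions(data.table::as.data.table(sites))
  miss <- setdiff(unique(dt$transcript_id), ann$transcript_id)
  if (length(miss)) stopf("metagene_coords: no annotation for %s", miss[1])
  cols <- if (axis == "full") c("transcript_id", "length") else
    c("transcript_id", "length", "cds_start", "cds_end")
  dt <- merge(dt, ann[, cols, with = FALSE], by = "transcript_id")
  if (any(dt$position < 0L | dt$position >= dt$length)) {
    stopf("metagene_coords: site position outside [0, length)")
  }
  if (axis == "full") {
    short <- dt$length < 2L
    if (any(short)) {
      warning(sprintf("metagene_coords: skipped %d site(s) on length-1 transcripts",
                      sum(short)), call. = FALSE)
      dt <- dt[!short]
    }
    dt[, coord := position / (length - 1)]
  } else {
    dt[, region := assign_region(position, cds_start, cds_end, length)]
    dt[region == "5UTR", coord := 0 + position / cds_start]
    dt[region == "CDS", coord := 1 + (position - cds_start) / (cds_end - cds_start)]
    dt[region == "3UTR", coord := 2 + (position - cds_end) / (length - cds_end)]
  }
  dt[]
}

#' Full-length metagene density profile of m6A sites
#'
#' Histogram of the full-axis coordinates (see [metagene_coords()]) over
#' `n_bins` equal bins (last bin right-closed), normalised to unit area per
#' condition.
#'
#' @inheritParams metagene_coords
#' @param n_bins number of bins (default 30).
#' @return `data.table` (`bin_left`, `bin_right`, `count`, `density`,
#'   `condition`) with attribute `axis = "full"`.
#' @export
metagene_full <- function(sites, annotations, n_bins = 30L) {
  dt <- metagene_coords(sites, annotations, axis = "full")
  make_profile(dt[, .(coord, condition)], seq(0, 1, length.out = n_bins + 1L),
               axis = "full")
}

#' Three-region (5'UTR / CDS / 3'UTR) metagene density profile
#'
#' Each region is scaled to unit length (see [metagene_coords()]); a site
#' exactly at `cds_start` belongs to the CDS, one at `cds_end` to the 3'UTR.
#' Transcripts lacking a UTR simply contribute no sites there. Unit area per
#' condition over `[0, 3]`.
#'
#' @inheritParams metagene_full
#' @param bins_per_region bins per region (default 20).
#' @return Profile `data.table` with attribute `axis = "regions"`.
#' @export
metagene_regions <- function(sites, annotations, bins_per_region = 20L) {
  dt <- metagene_coords(sites, annotations, axis = "regions")
  make_profile(dt[, .(coord, condition)],
               seq(0, 3, length.out = 3L * bins_per_region + 1L),
               axis = "regions")
}

#' Differential m6A deposition at RRACH sites
#'
#' Restricts a modification-call table to RRACH A positions and runs the
#' per-position differential caller, reporting the two-tier summary used in
#' such studies: how many sites are significant on the p-value gate alone and how
#' many additionally clear the |log2fc| threshold.
#'
#' @param x a [modcall_table()] with per-sample methylated-read counts.
#' @param sites RRACH site table from [find_rrach_sites()].
#' @inheritParams diffmod_scan
#' @return [diffmod_scan()] result restricted to RRACH sites, with attribute
#'   `two_tier = list(n_p_sig, n_lfc_sig)`.
#' @export
m6a_diff <- function(x, sites, min_cov = 50L, alpha = 0.05, lfc_min = 0.5,
                     adjust = c("none", "BH"), reference = NULL) {
  adjust <- match.arg(adjust)
  st <- data.table::as.data.table(sites)[, .(transcript_id, position)]
  dt <- data.table::as.data.table(x)
  sub <- dt[st, on = c("transcript_id", "position"), nomatch = NULL]
  if (!nrow(sub)) stopf("m6a_diff: no RRACH site has modification calls")
  sub <- modcall_table(sub, condition_map(x))
  res <- diffmod_scan(sub, min_cov = min_cov, alpha = alpha, lfc_min = lfc_min,
                      adjust = adjust, reference = reference)
  gate <- if (adjust == "BH") res$q_value else res$p_value
  data.table::setattr(res, "two_tier",
                      list(n_p_sig = sum(gate < alpha),
                           n_lfc_sig = sum(gate < alpha & abs(res$log2fc) > lfc_min)))
  res[]
}
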